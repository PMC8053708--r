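#' Terminus state space
#'
#' Small RNAs carry one of five 5' chemistries and one of four 3' chemistries.
#' Only molecules with a 5'-monophosphate and a 3'-hydroxyl can be ligated to
#' sequencing adapters; every other state is invisible to a standard library
#' prep until an enzyme converts it.
#'
#' @format Character vectors of the admissible state labels.
#' @name terminus-states
NULL

#' @rdname terminus-states
#' @export
FIVE_PRIME_STATES <- c("P", "OH", "cap_m7G", "cap_m3G", "ppp")

#' @rdname terminus-states
#' @export
THREE_PRIME_STATES <- c("OH", "P", "cP", "aa")

#' Methylated nucleoside kinds and the reference base each occurs on
#' @export
METHYL_KINDS <- c(m1A = "A", m3C = "C", m1G = "G")

#' Construct a tibble of terminus states
#'
#' @param five_prime,three_prime character vectors of state labels
#'   (recycled to a common length).
#' @return A tibble with columns `five_prime` and `three_prime`.
#' @examples
#' terminus_state("cap_m7G", "OH")
#' @export
terminus_state <- function(five_prime = "P", three_prime = "OH") {
  tbl <- tibble::tibble(five_prime = five_prime, three_prime = three_prime)
  validate_terminus(tbl)
  tbl
}

validate_terminus <- function(tbl) {
  stopifnot(is.data.frame(tbl),
            all(c("five_prime", "three_prime") %in% names(tbl)))
  bad5 <- setdiff(unique(tbl$five_prime), FIVE_PRIME_STATES)
  bad3 <- setdiff(unique(tbl$three_prime), THREE_PRIME_STATES)
  if (length(bad5) || length(bad3)) {
    stop("invalid terminus state(s): ",
         paste(c(bad5, bad3), collapse = ", "), call. = FALSE)
  }
  invisible(tbl)
}

#' All 20 terminus states
#'
#' @return A tibble enumerating the full 5 x 4 product of terminus states.
#' @export
all_terminus_states <- function() {
  tidyr::expand_grid(five_prime = FIVE_PRIME_STATES,
                     three_prime = THREE_PRIME_STATES)
}

#' Define an enzymatic treatment plan
#'
#' A plan is a subset of the four bench treatments. Deacylation is applied in
#' every named treatment group by default; the letters C, P, A in a label
#' stand for Cap-Clip, T4 PNK, and the AlkB demethylase mix respectively.
#'
#' @param cap_clip,pnk,alkb,deacylate logical flags for each treatment.
#' @param label optional plan label; derived from the flags when `NULL`.
#' @return An object of class `cpa_plan`.
#' @examples
#' treatment_plan(cap_clip = TRUE, pnk = TRUE, alkb = TRUE) # the full plan
#' plan_from_label("CA")
#' @export
treatment_plan <- function(cap_clip = FALSE, pnk = FALSE, alkb = FALSE,
                           deacylate = TRUE, label = NULL) {
  if (is.null(label)) {
    label <- paste0(if (cap_clip) "C" else "", if (pnk) "P" else "",
                    if (alkb) "A" else "")
    if (label == "") label <- "untreated"
  }
  structure(
    list(deacylate = deacylate, cap_clip = cap_clip, pnk = pnk, alkb = alkb,
         label = label),
    class = "cpa_plan"
  )
}

#' @rdname treatment_plan
#' @param x for `plan_from_label()`, a label such as `"CPA"`, `"CA"`, `"PA"`,
#'   `"CP"` or `"untreated"`.
#' @export
plan_from_label <- function(x) {
  if (identical(x, "untreated")) return(treatment_plan(label = "untreated"))
  letters_in <- strsplit(x, "")[[1]]
  bad <- setdiff(letters_in, c("C", "P", "A"))
  if (length(bad)) stop("unknown plan label: ", x, call. = FALSE)
  treatment_plan(cap_clip = "C" %in% letters_in,
                 pnk = "P" %in% letters_in,
                 alkb = "A" %in% letters_in,
                 label = x)
}

#' @export
print.cpa_plan <- function(x, ...) {
  on <- c("deacylate", "Cap-Clip", "T4 PNK", "AlkB")[
    c(x$deacylate, x$cap_clip, x$pnk, x$alkb)]
  cat("<treatment plan ", x$label, "> ",
      if (length(on)) paste(on, collapse = " + ") else "none", "\n", sep = "")
  invisible(x)
}

#' Apply enzymatic end conversions to terminus states
#'
#' Implements the terminus algebra of the bench workflow, in the fixed order
#' deacylation, Cap-Clip, T4 PNK (AlkB acts on methyl sites, not termini):
#' \itemize{
#'   \item deacylation: 3'-aa -> 3'-OH
#'   \item Cap-Clip: 5' m7G cap, m3G cap and 5'-ppp -> 5'-P
#'   \item T4 PNK: 5'-OH -> 5'-P; 3'-P and 3'-cP -> 3'-OH
#' }
#' Each enabled enzyme converts a given molecule with its per-enzyme
#' efficiency (default 1, i.e. deterministic). Randomness, if any, uses the
#' current R random number generator; seed it for reproducibility.
#'
#' @param termini a data frame with columns `five_prime` and `three_prime`
#'   (one row per molecule); other columns are carried through.
#' @param plan a [treatment_plan()].
#' @param efficiencies named numeric vector of per-enzyme conversion
#'   probabilities, names among `deacylate`, `cap_clip`, `pnk`.
#' @return The input tibble with converted `five_prime`/`three_prime`.
#' @examples
#' apply_treatments(terminus_state("cap_m7G", "OH"), plan_from_label("C"))
#' @export
apply_treatments <- function(termini, plan,
                             efficiencies = c(deacylate = 1, cap_clip = 1,
                                              pnk = 1)) {
  validate_terminus(termini)
  stopifnot(inherits(plan, "cpa_plan"))
  eff <- function(nm) {
    e <- if (nm %in% names(efficiencies)) efficiencies[[nm]] else 1
    stopifnot(e >= 0, e <= 1)
    e
  }
  n <- nrow(termini)
  f5 <- termini$five_prime
  f3 <- termini$three_prime
  hit <- function(mask, e) mask & (if (e >= 1) TRUE else stats::runif(n) < e)

  if (isTRUE(plan$deacylate)) {
    f3[hit(f3 == "aa", eff("deacylate"))] <- "OH"
  }
  if (isTRUE(plan$cap_clip)) {
    f5[hit(f5 %in% c("cap_m7G", "cap_m3G", "ppp"), eff("cap_clip"))] <- "P"
  }
  if (isTRUE(plan$pnk)) {
    e <- eff("pnk")
    f5[hit(f5 == "OH", e)] <- "P"
    f3[hit(f3 %in% c("P", "cP"), e)] <- "OH"
  }
  termini$five_prime <- f5
  termini$three_prime <- f3
  termini
}

#' Demethylate sites according to a treatment plan
#'
#' AlkB removes m1A/m3C/m1G marks; each site on each molecule is erased
#' independently with probability `alkb_efficiency` when the plan includes
#' the AlkB mix. Site presence/stoichiometry is resolved upstream: the input
#' here is one row per *methylated* molecule-site.
#'
#' @param sites tibble of molecule-level methyl sites (any columns; one row
#'   per methylated site on a molecule).
#' @param plan a [treatment_plan()].
#' @param alkb_efficiency per-site demethylation probability in \[0, 1\].
#' @return `sites` restricted to the rows that remain methylated.
#' @export
apply_demethylation <- function(sites, plan, alkb_efficiency = 1) {
  stopifnot(inherits(plan, "cpa_plan"),
            alkb_efficiency >= 0, alkb_efficiency <= 1)
  if (!isTRUE(plan$alkb) || nrow(sites) == 0) return(sites)
  keep <- stats::runif(nrow(sites)) >= alkb_efficiency
  sites[keep, , drop = FALSE]
}

#' Is a terminus state ligatable?
#'
#' Adapter ligation requires a 5'-monophosphate and a 3'-hydroxyl.
#'
#' @param termini a data frame with `five_prime`/`three_prime` columns.
#' @return Logical vector, one element per row.
#' @examples
#' is_ligatable(terminus_state("P", "OH"))   # TRUE
#' is_ligatable(terminus_state("OH", "OH"))  # FALSE
#' @export
is_ligatable <- function(termini) {
  validate_terminus(termini)
  termini$five_prime == "P" & termini$three_prime == "OH"
}
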