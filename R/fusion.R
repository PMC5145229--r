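# Sensor-combination enumeration and decision fusion. A trial is declared a
# fall by a combination only if every sensor in it individually declares a
# fall (AND policy); this is the rule used throughout the evaluation. An OR
# policy is available strictly for comparison experiments.

#' Enumerate sensor-position combinations
#'
#' All non-empty subsets of the given positions, in a deterministic order:
#' by subset size, then lexicographically by the canonical position order
#' (thigh pocket, chest, waist, wrist, ankle) — the row order of the
#' combination results table. Five positions yield 31 (2^5 - 1) subsets.
#'
#' @param positions character vector of positions (default all five).
#' @return A list of character vectors, each a combination in canonical
#'   order.
#' @examples
#' length(enumerateCombinations())                 # 31
#' enumerateCombinations(c("wrist", "waist"))[[3]] # c("waist", "wrist")
#' @export
enumerateCombinations <- function(positions = sensorPositions()) {
  if (length(positions) < 1L) stop("positions must be non-empty")
  positions <- canonicalPositions(positions)
  out <- list()
  for (k in seq_along(positions)) {
    sets <- utils::combn(positions, k, simplify = FALSE)
    out <- c(out, sets)  # combn on canonically ordered input is lexicographic
  }
  out
}

#' Fuse per-sensor decisions over a combination
#'
#' `fuseAnd()` applies the AND policy: the fused decision is `TRUE` only if
#' every position in the combination decided `TRUE`. A missing decision for
#' a required position is an error (the trial lacks that stream).
#' `fuseDecisions()` additionally offers the OR policy for comparison runs.
#'
#' @param decisions named logical vector, one decision per position.
#' @param combination character vector of positions to fuse over.
#' @param policy `"and"` (the evaluation's decision rule) or `"or"`.
#' @return logical(1).
#' @examples
#' fuseAnd(c(wrist = TRUE, waist = TRUE), c("wrist", "waist"))  # TRUE
#' fuseAnd(c(wrist = TRUE, waist = FALSE), c("wrist", "waist")) # FALSE
#' @export
fuseAnd <- function(decisions, combination) {
  fuseDecisions(decisions, combination, policy = "and")
}

#' @rdname fuseAnd
#' @export
fuseDecisions <- function(decisions, combination, policy = c("and", "or")) {
  policy <- match.arg(policy)
  combination <- canonicalPositions(combination)
  missing <- setdiff(combination, names(decisions))
  if (length(missing))
    stop("no decision for position(s): ", paste(missing, collapse = ", "))
  d <- decisions[combination]
  if (anyNA(d)) stop("NA decision in combination")
  if (policy == "and") all(d) else any(d)
}
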