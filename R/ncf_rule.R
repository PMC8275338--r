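#' Nested canalyzing update rule
#'
#' An NCF rule is an ordered cascade of canalyzing tuples
#' `(regulator, I, O)`: the rule output is the canalyzed value `O` of the
#' first tuple whose regulator currently equals its canalyzing value `I`,
#' and the default output if no tuple fires. By convention the default is
#' the complement of the last tuple's canalyzed value; `permissive = TRUE`
#' accepts (with a warning) rule files that break the convention.
#'
#' @param target 1-based index of the regulated gene.
#' @param regulators integer vector of 1-based regulator indices, pairwise
#'   distinct, none equal to `target` (no self-loops).
#' @param I,O canalyzing / canalyzed bits (0/1), one per regulator.
#' @param default_out default output bit; `NULL` derives `1 - O[k]`.
#' @param permissive accept a `default_out` that differs from `1 - O[k]`.
#' @return An object of class `ncf_rule`.
#' @examples
#' r <- ncf_rule(3, regulators = c(1, 2), I = c(1, 0), O = c(1, 1))
#' evaluate_rule(r, c(0, 0, 1))
#' @export
ncf_rule <- function(target, regulators, I, O, default_out = NULL,
                     permissive = FALSE) {
  target <- as.integer(target)
  regulators <- as.integer(regulators)
  I <- as.integer(I)
  O <- as.integer(O)
  k <- length(regulators)
  if (k < 1L) stop("an NCF rule needs at least one canalyzing tuple")
  if (length(I) != k || length(O) != k)
    stop("regulators, I and O must have equal length")
  if (anyDuplicated(regulators))
    stop("regulators within a rule must be pairwise distinct")
  if (any(regulators == target))
    stop("self-loops are not allowed (gene ", target, ")")
  if (!all(I %in% 0:1) || !all(O %in% 0:1))
    stop("canalyzing and canalyzed values must be 0 or 1")
  derived <- 1L - O[k]
  if (is.null(default_out)) {
    default_out <- derived
  } else {
    default_out <- as.integer(default_out)
    if (!default_out %in% 0:1) stop("default_out must be 0 or 1")
    if (default_out != derived) {
      if (!permissive)
        stop("default output must be the complement of the last canalyzed value")
      warning("default output of gene ", target,
              " differs from the complement of its last canalyzed value")
    }
  }
  structure(list(target = target, regulators = regulators, I = I, O = O,
                 default_out = default_out),
            class = "ncf_rule")
}

#' Evaluate an NCF rule on a network state
#'
#' Walks the canalyzing cascade: returns the canalyzed value of the first
#' tuple whose regulator state equals its canalyzing value, or the default
#' output if none fires.
#'
#' @param rule an [ncf_rule()].
#' @param state integer 0/1 vector of gene states, indexed by gene.
#' @return A single bit (integer 0 or 1).
#' @export
evaluate_rule <- function(rule, state) {
  stopifnot(inherits(rule, "ncf_rule"))
  if (any(rule$regulators > length(state)))
    stop("regulator index out of range for the given state")
  for (m in seq_along(rule$regulators)) {
    if (state[rule$regulators[m]] == rule$I[m]) return(rule$O[m])
  }
  rule$default_out
}

# Sign of the regulation carried by one tuple: matching canalyzing and
# canalyzed bits mean activation, opposing bits inhibition.
tuple_sign <- function(I, O) ifelse(I == O, 1L, -1L)

#' @export
format.ncf_rule <- function(x, ...) {
  tup <- paste0("(v", x$regulators, ",", x$I, ",", x$O, ")", collapse = "")
  paste0("v", x$target, " = ", tup, ":", x$default_out)
}

#' @export
print.ncf_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
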