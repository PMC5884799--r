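#' Phenotype group labels
#'
#' The controlled vocabulary for dataset-comparison groups: the two
#' multiple-sclerosis analysis groups (`non_treated`, `treated`), their union
#' (`general`) and the three comparator disease groups (`virus`,
#' `inflammation`, `autoimmune`).
#'
#' @return Character vector of valid group labels.
#' @export
groupLabels <- function() {
  c("general", "non_treated", "treated", "virus", "inflammation", "autoimmune")
}

.assertGroupLabel <- function(label) {
  if (length(label) != 1L || !label %in% groupLabels()) {
    stop("unknown group label: ", paste(label, collapse = ", "),
         " (must be one of ", paste(groupLabels(), collapse = ", "), ")",
         call. = FALSE)
  }
  label
}

.assertProbability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a single value in [0, 1]", call. = FALSE)
  }
  x
}

# deterministic substream seed below 2^31, derived from a root seed
.deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
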