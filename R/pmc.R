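#' First-level variable value from binary sub-variable flags
#'
#' A primary variable's first-level value is the arithmetic mean of its
#' binary sub-variable flags: the fraction of that dimension's criteria
#' the policy satisfies. Full precision is kept here; any rounding
#' happens at index computation (see [pmc_index()]).
#'
#' @param subscores numeric vector of 0/1 flags (non-empty).
#' @return A fraction in \[0, 1\].
#' @examples
#' first_level_score(c(1, 1, 1, 1, 0)) # 4 of 5 criteria -> 0.8
#' @export
first_level_score <- function(subscores) {
  if (!length(subscores)) stop("no sub-variable flags given", call. = FALSE)
  if (!is_binary(subscores)) {
    stop("sub-variable flags must all be 0 or 1", call. = FALSE)
  }
  sum(subscores) / length(subscores)
}

#' PMC index from first-level values
#'
#' The PMC (Policy Modeling Consistency) index is the sum of a policy's
#' first-level values; with n primary variables it ranges over
#' \[0, n\]. Two rounding conventions are offered:
#'
#' * `"report-parity"` (default): each first-level value is rounded
#'   half-up to `digits` decimals (2 by default) before summation. This
#'   reproduces published score tables, which print first-level values
#'   to two decimals and report the PMC index as the sum of the printed
#'   values (e.g. 2/3 enters as 0.67).
#' * `"full-precision"`: the exact fractions are summed.
#'
#' The two conventions differ by at most n * 5e-3 at two decimals.
#'
#' @param first_level numeric vector of first-level values in \[0, 1\].
#' @param rounding `"report-parity"` or `"full-precision"`.
#' @param digits decimals used by report-parity rounding.
#' @return The PMC index, a number in \[0, length(first_level)\].
#' @examples
#' x <- c(0.67, 1, 0.25, 1, 0.5, 0.5, 0.67, 0.5, 0.8)
#' pmc_index(x)                      # 5.89
#' pmc_index(x, "full-precision")    # 5.89 (inputs already 2-dp)
#' @export
pmc_index <- function(first_level,
                      rounding = c("report-parity", "full-precision"),
                      digits = 2) {
  rounding <- match.arg(rounding)
  if (anyNA(first_level) || any(first_level < 0 | first_level > 1)) {
    stop("first-level values must lie in [0, 1]", call. = FALSE)
  }
  if (rounding == "report-parity") {
    sum(round_half_up(first_level, digits))
  } else {
    sum(first_level)
  }
}

#' Grade a PMC index value
#'
#' For the default 9-primary framework the index is classified on four
#' intervals: Bad \[0, 4), Good \[4, 6), Excellent \[6, 8), Perfect
#' \[8, 9\]. Intervals are half-open on the left; the top interval is
#' closed so a full score is classifiable. "Acceptable" in prose
#' corresponds to Good. Custom frameworks (a different number of
#' primaries, hence a different index range) must supply their own
#' `breaks`.
#'
#' @param pmc numeric vector of PMC index values.
#' @param breaks increasing cut-points, first 0, last the maximum
#'   attainable index; length `length(labels) + 1`.
#' @param labels grade labels, worst first.
#' @return An ordered factor of grades.
#' @examples
#' pmc_grade(c(3.93, 5.89, 7.91, 9))
#' @export
pmc_grade <- function(pmc, breaks = c(0, 4, 6, 8, 9),
                      labels = c("Bad", "Good", "Excellent", "Perfect")) {
  if (length(breaks) != length(labels) + 1L || is.unsorted(breaks, strictly = TRUE)) {
    stop("`breaks` must be strictly increasing with length(labels) + 1 entries",
         call. = FALSE)
  }
  if (anyNA(pmc) || any(pmc < breaks[1L] | pmc > breaks[length(breaks)])) {
    stop(sprintf("PMC value outside [%g, %g]", breaks[1L],
                 breaks[length(breaks)]), call. = FALSE)
  }
  # right = FALSE gives [a, b) intervals; the top interval is closed via
  # include.lowest (which closes the outer boundary under right = FALSE)
  cut(pmc, breaks = breaks, labels = labels, right = FALSE,
      include.lowest = TRUE, ordered_result = TRUE)
}

#' Score a policy corpus with the PMC index model
#'
#' `pmc()` is the model-fitting entry point: it takes a validated
#' binary coding matrix (see [read_coding_matrix()]), computes each
#' policy's first-level values (per-primary means of the 0/1
#' sub-variable flags), sums them into the PMC index under the chosen
#' rounding convention, and grades the result. The returned object has
#' `print()`, `summary()`, `as.data.frame()` and `plot()` methods;
#' `summary()` produces the corpus aggregates (mean index, grade
#' counts and percentages, per-primary means).
#'
#' @param x a `pmc_coding` object, or (for `pmc_from_first_level`) a
#'   numeric vector/matrix of first-level values.
#' @param rounding,digits see [pmc_index()].
#' @param breaks,labels see [pmc_grade()]. Defaults apply to 9-primary
#'   schemas; other schemas must supply cut-points.
#' @return A `pmc_scores` object: list with `first_level` (policies x
#'   primaries matrix, full precision), `pmc` (named vector), `grade`
#'   (ordered factor), `rounding`, `digits`, `schema_name`,
#'   `primary_ids`.
#' @examples
#' sch <- default_schema()
#' gen <- generate_matrix(matrix_config(n_policies = 5, seed = 1), sch)
#' fit <- pmc(gen$coding)
#' fit
#' summary(fit)
#' @export
pmc <- function(x, rounding = c("report-parity", "full-precision"),
                digits = 2, breaks = NULL, labels = NULL) {
  stopifnot(inherits(x, "pmc_coding"))
  rounding <- match.arg(rounding)
  schema <- x$schema
  cnt <- subvariable_counts(schema)
  pid <- primary_ids(schema)
  fl <- matrix(NA_real_, nrow = nrow(x$values), ncol = length(pid),
               dimnames = list(rownames(x$values), pid))
  for (p in schema$primaries) {
    sids <- vapply(p$subvariables, `[[`, character(1L), "id")
    fl[, p$id] <- rowSums(x$values[, sids, drop = FALSE]) / length(sids)
  }
  new_pmc_scores(fl, rounding, digits, breaks, labels,
                 schema_name = schema$name)
}

#' @rdname pmc
#' @param policy_id identifiers for the rows of `x` when `x` is a bare
#'   matrix/vector of first-level values.
#' @export
pmc_from_first_level <- function(x, policy_id = NULL,
                                 rounding = c("report-parity", "full-precision"),
                                 digits = 2, breaks = NULL, labels = NULL) {
  rounding <- match.arg(rounding)
  if (is.vector(x)) x <- matrix(x, nrow = 1L,
                                dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (anyNA(x) || any(x < 0 | x > 1)) {
    stop("first-level values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (!is.null(policy_id)) {
    if (length(policy_id) != nrow(x)) {
      stop("length(policy_id) must equal the number of rows", call. = FALSE)
    }
    rownames(x) <- policy_id
  } else if (is.null(rownames(x))) {
    rownames(x) <- paste0("P", seq_len(nrow(x)))
  }
  new_pmc_scores(x, rounding, digits, breaks, labels,
                 schema_name = sprintf("%d first-level values", ncol(x)))
}

new_pmc_scores <- function(first_level, rounding, digits, breaks, labels,
                           schema_name) {
  np <- ncol(first_level)
  if (is.null(breaks)) {
    if (np != 9L) {
      stop("default grade cut-points apply to 9-primary schemas only; ",
           "supply `breaks` (and `labels`) for this schema", call. = FALSE)
    }
    breaks <- c(0, 4, 6, 8, 9)
  }
  if (is.null(labels)) labels <- c("Bad", "Good", "Excellent", "Perfect")
  idx <- apply(first_level, 1L, pmc_index, rounding = rounding,
               digits = digits)
  structure(list(first_level = first_level,
                 pmc = idx,
                 grade = pmc_grade(idx, breaks, labels),
                 rounding = rounding, digits = digits,
                 breaks = breaks, labels = labels,
                 schema_name = schema_name,
                 primary_ids = colnames(first_level)),
            class = "pmc_scores")
}

#' @export
print.pmc_scores <- function(x, n = 6L, ...) {
  cat(sprintf("PMC index scores (%s rounding), %d policies, schema: %s\n",
              x$rounding, length(x$pmc), x$schema_name))
  df <- as.data.frame(x)
  print(utils::head(df, n), row.names = FALSE, digits = 4)
  if (nrow(df) > n) cat(sprintf("  ... %d more policies\n", nrow(df) - n))
  invisible(x)
}

#' @export
as.data.frame.pmc_scores <- function(x, ...) {
  data.frame(policy_id = rownames(x$first_level),
             x$first_level,
             pmc = unname(x$pmc),
             grade = as.character(x$grade),
             stringsAsFactors = FALSE, row.names = NULL,
             check.names = FALSE)
}

#' Corpus-level aggregates of PMC scores
#'
#' Summarises a scored corpus: number of policies, mean PMC index,
#' grade counts and percentages (percentages to one decimal, half-up),
#' and per-primary mean first-level values (the "average value" row of
#' a score table).
#'
#' @param object a `pmc_scores` object.
#' @param ... unused.
#' @return A `summary.pmc_scores` list with `n_policies`, `mean_pmc`,
#'   `grade_counts`, `grade_percent`, `variable_means`, `range`.
#' @export
summary.pmc_scores <- function(object, ...) {
  if (!length(object$pmc)) stop("no policies scored", call. = FALSE)
  counts <- table(object$grade)
  structure(list(n_policies = length(object$pmc),
                 mean_pmc = mean(object$pmc),
                 grade_counts = counts,
                 grade_percent = round_half_up(100 * as.numeric(counts) /
                                                 length(object$pmc), 1L),
                 variable_means = colMeans(object$first_level),
                 range = range(object$pmc),
                 rounding = object$rounding),
            class = "summary.pmc_scores")
}

#' @export
print.summary.pmc_scores <- function(x, ...) {
  cat(sprintf("PMC corpus summary (%d policies, %s rounding)\n",
              x$n_policies, x$rounding))
  cat(sprintf("  mean PMC index: %.3f   range: [%.2f, %.2f]\n",
              x$mean_pmc, x$range[1L], x$range[2L]))
  cat("  grades:\n")
  for (i in seq_along(x$grade_counts)) {
    cat(sprintf("    %-10s %4d  (%.1f%%)\n",
                names(x$grade_counts)[i], x$grade_counts[i],
                x$grade_percent[i]))
  }
  cat("  per-variable means:\n")
  m <- x$variable_means
  cat(sprintf("    %s\n", paste(sprintf("%s=%.3f", names(m), m),
                                collapse = "  ")))
  invisible(x)
}

#' @rdname pmc
#' @param object,y,policy see methods; `plot()` renders the PMC surface
#'   of one policy (see [pmc_surface()]).
#' @param ... passed on to [plot.pmc_surface()].
#' @export
plot.pmc_scores <- function(x, policy = 1L, ...) {
  plot(pmc_surface(x, policy), ...)
}
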