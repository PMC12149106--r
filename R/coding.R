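#' Coding matrices: the multi-input-output table
#'
#' The multi-input-output table is the complete policies x sub-variables
#' binary matrix from which every PMC score derives: cell (p, s) is 1
#' when policy p satisfies sub-variable s, else 0. Missing cells are
#' illegal — the first-level averages assume fully coded columns — so
#' the reader rejects blanks and non-binary cells rather than imputing.
#'
#' @param policies a data.frame with columns `policy_id` (unique),
#'   and optionally `title`, `issuer`, `year`.
#' @param values a numeric matrix of 0/1 flags, one row per policy in
#'   the same order, columns named by sub-variable id covering the
#'   schema exactly.
#' @param schema a [pmc_schema][load_schema] the matrix is coded against.
#' @return A `pmc_coding` object: list with `policies`, `values`
#'   (integer matrix, rownames = policy ids), `schema`.
#' @examples
#' sch <- load_schema("
#' name: toy
#' primaries:
#'   - id: A
#'     subvariables: [{id: A_1}, {id: A_2}]
#' ")
#' cm <- coding_matrix(data.frame(policy_id = c("P1", "P2")),
#'                     matrix(c(1, 0, 1, 1), 2, 2,
#'                            dimnames = list(NULL, c("A_1", "A_2"))),
#'                     sch)
#' column_means(cm)
#' @export
coding_matrix <- function(policies, values, schema) {
  stopifnot(inherits(schema, "pmc_schema"), is.data.frame(policies))
  if (!"policy_id" %in% names(policies)) {
    stop("`policies` must have a policy_id column", call. = FALSE)
  }
  policies$policy_id <- as.character(policies$policy_id)
  if (anyDuplicated(policies$policy_id)) {
    stop(sprintf("duplicate policy_id '%s'",
                 policies$policy_id[duplicated(policies$policy_id)][1L]),
         call. = FALSE)
  }
  if ("year" %in% names(policies)) {
    yr <- policies$year[!is.na(policies$year)]
    if (length(yr) && any(yr < 1900 | yr > 2100)) {
      stop("policy year outside 1900-2100", call. = FALSE)
    }
  }
  values <- as.matrix(values)
  sid <- subvariable_ids(schema)
  missing_cols <- setdiff(sid, colnames(values))
  if (length(missing_cols)) {
    stop(sprintf("schema mismatch: missing sub-variable column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(colnames(values), sid)
  if (length(extra)) {
    stop(sprintf("schema mismatch: unknown column(s) %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  values <- values[, sid, drop = FALSE]
  if (nrow(values) != nrow(policies)) {
    stop("`values` and `policies` disagree on the number of policies",
         call. = FALSE)
  }
  bad <- which(is.na(values) | !(values %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("coding error: cell (%s, %s) is '%s', must be 0 or 1",
                 policies$policy_id[bad[1L, 1L]], colnames(values)[bad[1L, 2L]],
                 format(values[bad[1L, , drop = FALSE]])), call. = FALSE)
  }
  storage.mode(values) <- "integer"
  rownames(values) <- policies$policy_id
  structure(list(policies = policies, values = values, schema = schema),
            class = "pmc_coding")
}

#' Read and write a coding matrix as CSV
#'
#' The on-disk dialect is comma-separated UTF-8: first column
#' `policy_id`, optional `title`, `issuer`, `year` metadata columns, then
#' one 0/1 column per sub-variable named by its id. Cells outside
#' \{0, 1\} (including blanks) are rejected with the offending row and
#' column named. A read-write-read round trip reproduces the matrix
#' exactly.
#'
#' @param path CSV file path.
#' @param schema a [pmc_schema][load_schema].
#' @return `read_coding_matrix()` a `pmc_coding`; `write_coding_matrix()`
#'   the path, invisibly.
#' @export
read_coding_matrix <- function(path, schema) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!"policy_id" %in% names(df)) {
    stop("coding matrix must have a policy_id column", call. = FALSE)
  }
  sid <- subvariable_ids(schema)
  missing_cols <- setdiff(sid, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema mismatch: file lacks column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  meta_cols <- intersect(c("policy_id", "title", "issuer", "year"), names(df))
  policies <- df[meta_cols]
  if ("year" %in% names(policies)) {
    policies$year <- suppressWarnings(as.integer(policies$year))
  }
  vals <- df[sid]
  for (j in seq_along(vals)) {
    v <- trimws(vals[[j]])
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop(sprintf("coding error: row %d (policy '%s'), column '%s': '%s' is not 0/1",
                   i, df$policy_id[i], sid[j], v[i]), call. = FALSE)
    }
    vals[[j]] <- as.integer(v)
  }
  coding_matrix(policies, as.matrix(vals), schema)
}

#' @rdname read_coding_matrix
#' @param coding a `pmc_coding` object.
#' @export
write_coding_matrix <- function(coding, path) {
  stopifnot(inherits(coding, "pmc_coding"))
  df <- cbind(coding$policies, as.data.frame(coding$values),
              stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Rule-based coding of raw policy texts
#'
#' A transparent, deterministic alternative to manual coding: each rule
#' ties one sub-variable to a set of literal keyword patterns; the cell
#' is set to 1 when the document text contains any (mode "any") or all
#' (mode "all") of the patterns as substrings. Matching normalises by
#' stripping whitespace and case-folding Latin letters only — no
#' stemming, no segmentation — so a rule set is auditable by eye.
#' Sub-variables without a rule code as 0.
#'
#' @param texts named character vector or list, `policy_id` -> document
#'   text.
#' @param rules list of rules, each `list(subvariable_id=, patterns=,
#'   mode=)` with mode "any" (default) or "all".
#' @param schema a [pmc_schema][load_schema].
#' @return A `pmc_coding` with one row per document, in input order.
#' @examples
#' sch <- default_schema()
#' rules <- list(list(subvariable_id = "X2_1", patterns = "long-term"))
#' m <- apply_rules(c(P1 = "A long-term plan.", P2 = ""), rules, sch)
#' m$values["P1", "X2_1"]
#' @export
apply_rules <- function(texts, rules, schema) {
  stopifnot(inherits(schema, "pmc_schema"))
  texts <- unlist(as.list(texts))
  if (is.null(names(texts)) || any(!nzchar(names(texts)))) {
    stop("`texts` must be named by policy_id", call. = FALSE)
  }
  sid <- subvariable_ids(schema)
  for (r in rules) {
    if (!r$subvariable_id %in% sid) {
      stop(sprintf("rule references unknown sub-variable '%s'",
                   r$subvariable_id), call. = FALSE)
    }
    if (is.null(r$patterns) || !length(r$patterns)) {
      stop(sprintf("rule for '%s' has no patterns", r$subvariable_id),
           call. = FALSE)
    }
  }
  norm <- function(x) tolower(gsub("[[:space:]]+", "", x))
  ntexts <- vapply(texts, norm, character(1L))
  values <- matrix(0L, nrow = length(texts), ncol = length(sid),
                   dimnames = list(names(texts), sid))
  for (r in rules) {
    mode <- r$mode %||% "any"
    hits <- vapply(ntexts, function(tx) {
      m <- vapply(r$patterns, function(p) {
        grepl(norm(p), tx, fixed = TRUE)
      }, logical(1L))
      if (identical(mode, "all")) all(m) else any(m)
    }, logical(1L))
    values[, r$subvariable_id] <- values[, r$subvariable_id] | hits
  }
  storage.mode(values) <- "integer"
  coding_matrix(data.frame(policy_id = names(texts),
                           stringsAsFactors = FALSE),
                values, schema)
}

#' @rdname apply_rules
#' @param path YAML file with a top-level `rules:` list of
#'   \{subvariable_id, patterns, mode\} entries.
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- raw$rules %||% raw
  lapply(rules, function(r) {
    list(subvariable_id = as.character(r$subvariable_id),
         patterns = as.character(r$patterns),
         mode = as.character(r$mode %||% "any"))
  })
}

#' Per-sub-variable satisfaction fractions
#'
#' Column means of the binary matrix: the fraction of policies
#' satisfying each sub-variable, the quantity behind statements such as
#' "82.4% were identified as long-term policies".
#'
#' @param coding a `pmc_coding` object.
#' @return Named numeric vector in \[0, 1\], one entry per sub-variable.
#' @export
column_means <- function(coding) {
  stopifnot(inherits(coding, "pmc_coding"))
  if (nrow(coding$values) == 0L) {
    stop("empty coding matrix", call. = FALSE)
  }
  colMeans(coding$values)
}

#' Lint mutually exclusive sub-variable blocks
#'
#' Some sub-variable groups are categorical in substance (e.g. the four
#' issuer flags: exactly one of state / region / department / other
#' applies per policy) even though the matrix format keeps them as
#' independent binaries. This lint reports, per configured block, the
#' policies whose row sum over the block differs from 1. It never
#' modifies the matrix.
#'
#' @param coding a `pmc_coding` object.
#' @param blocks list of character vectors of sub-variable ids.
#' @return A data.frame (block, policy_id, row_sum) of violations;
#'   zero rows when every block is satisfied.
#' @export
check_exclusive_blocks <- function(coding, blocks) {
  stopifnot(inherits(coding, "pmc_coding"))
  out <- lapply(seq_along(blocks), function(b) {
    ids <- blocks[[b]]
    missing_ids <- setdiff(ids, colnames(coding$values))
    if (length(missing_ids)) {
      stop(sprintf("block %d references unknown sub-variable '%s'",
                   b, missing_ids[1L]), call. = FALSE)
    }
    rs <- rowSums(coding$values[, ids, drop = FALSE])
    bad <- which(rs != 1L)
    if (!length(bad)) return(NULL)
    data.frame(block = paste(ids, collapse = "+"),
               policy_id = rownames(coding$values)[bad],
               row_sum = unname(rs[bad]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(block = character(), policy_id = character(),
                      row_sum = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.pmc_coding <- function(x, ...) {
  cat(sprintf("PMC coding matrix: %d policies x %d sub-variables (schema: %s)\n",
              nrow(x$values), ncol(x$values), x$schema$name))
  cat(sprintf("  cells set: %d of %d (%.1f%%)\n", sum(x$values),
              length(x$values), 100 * mean(x$values)))
  invisible(x)
}
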