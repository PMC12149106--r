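#' Evaluation schemas: the two-level variable framework
#'
#' A PMC evaluation schema is a two-level tree: primary variables (the
#' evaluation dimensions, e.g. "Nature of policy"), each holding an
#' ordered set of binary sub-variables with an evaluation criterion
#' ("Determine if the policy reflects guidance"). Every sub-variable is
#' scored 0/1 per policy; a primary's first-level value is the mean of
#' its sub-variables, so the per-primary sub-variable count is the
#' divisor used throughout scoring. The maximum attainable PMC index
#' equals the number of primaries.
#'
#' Schemas are data, not code: any number of primaries and sub-variables
#' is allowed. The framework used for Chinese traditional-medicine drug
#' registration policies (9 primaries, 41 sub-variables, per-primary
#' counts 6, 3, 4, 4, 6, 6, 3, 4, 5) ships with the package; see
#' [default_schema()].
#'
#' @param source path to a schema YAML file, or a YAML string.
#' @return A `pmc_schema` object: a list with elements `name`,
#'   `primaries` (each a list with `id`, `label`, `subvariables`), and
#'   `total_subvariables`.
#' @examples
#' sch <- default_schema()
#' sch
#' n_subvariables(sch)
#' @seealso [write_schema()], [read_coding_matrix()]
#' @export
load_schema <- function(source) {
  raw <- if (length(source) == 1L && file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (is.null(raw$primaries) || length(raw$primaries) == 0L) {
    stop("schema error: no primary variables defined", call. = FALSE)
  }
  primaries <- lapply(raw$primaries, function(p) {
    if (is.null(p$id) || !nzchar(p$id)) {
      stop("schema error: primary variable without an id", call. = FALSE)
    }
    if (is.null(p$subvariables) || length(p$subvariables) == 0L) {
      stop(sprintf("schema error: primary '%s' has no sub-variables", p$id),
           call. = FALSE)
    }
    subs <- lapply(p$subvariables, function(s) {
      if (is.null(s$id) || !nzchar(s$id)) {
        stop(sprintf("schema error: sub-variable of '%s' without an id", p$id),
             call. = FALSE)
      }
      list(id = as.character(s$id),
           label = as.character(s$label %||% s$id),
           criterion = as.character(s$criterion %||% ""))
    })
    list(id = as.character(p$id),
         label = as.character(p$label %||% p$id),
         subvariables = subs)
  })
  schema <- structure(
    list(name = as.character(raw$name %||% "unnamed schema"),
         primaries = primaries,
         total_subvariables = sum(vapply(primaries,
                                         function(p) length(p$subvariables),
                                         integer(1L)))),
    class = "pmc_schema")
  validate_schema(schema)
  schema
}

validate_schema <- function(schema) {
  pid <- primary_ids(schema)
  if (anyDuplicated(pid)) {
    stop(sprintf("schema error: duplicate primary id '%s'",
                 pid[duplicated(pid)][1L]), call. = FALSE)
  }
  sid <- subvariable_ids(schema)
  if (anyDuplicated(sid)) {
    stop(sprintf("schema error: duplicate sub-variable id '%s'",
                 sid[duplicated(sid)][1L]), call. = FALSE)
  }
  invisible(schema)
}

#' The packaged policy-evaluation framework
#'
#' Returns the two-level evaluation framework for Chinese
#' traditional-medicine drug registration policies: 9 primary variables
#' (nature, timeliness, issuing institution, object, function, content,
#' approach, incentive method, scientificity) holding 41 binary
#' sub-variables in counts (6, 3, 4, 4, 6, 6, 3, 4, 5). With this schema
#' the PMC index ranges over \[0, 9\].
#'
#' @return A `pmc_schema` object.
#' @examples
#' sch <- default_schema()
#' vapply(sch$primaries, function(p) length(p$subvariables), integer(1))
#' @export
default_schema <- function() {
  load_schema(system.file("extdata", "tcm_registration_schema.yaml",
                          package = "pmcindex", mustWork = TRUE))
}

#' @rdname load_schema
#' @param schema a `pmc_schema` object.
#' @param path file to write the schema YAML to.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "pmc_schema"))
  yaml::write_yaml(list(name = schema$name, primaries = schema$primaries),
                   path)
  invisible(path)
}

#' @rdname load_schema
#' @export
n_primaries <- function(schema) length(schema$primaries)

#' @rdname load_schema
#' @export
n_subvariables <- function(schema) schema$total_subvariables

primary_ids <- function(schema) {
  vapply(schema$primaries, `[[`, character(1L), "id")
}

subvariable_ids <- function(schema) {
  unlist(lapply(schema$primaries, function(p) {
    vapply(p$subvariables, `[[`, character(1L), "id")
  }), use.names = FALSE)
}

# sub-variable counts per primary, named by primary id
subvariable_counts <- function(schema) {
  n <- vapply(schema$primaries, function(p) length(p$subvariables),
              integer(1L))
  names(n) <- primary_ids(schema)
  n
}

#' @export
print.pmc_schema <- function(x, ...) {
  cnt <- subvariable_counts(x)
  cat(sprintf("PMC evaluation schema: %s\n", x$name))
  cat(sprintf("  %d primary variables, %d binary sub-variables\n",
              n_primaries(x), n_subvariables(x)))
  for (p in x$primaries) {
    cat(sprintf("  %-4s %-40s (%d sub-variables)\n",
                p$id, p$label, length(p$subvariables)))
  }
  cat(sprintf("  maximum attainable PMC index: %d\n", n_primaries(x)))
  invisible(x)
}
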