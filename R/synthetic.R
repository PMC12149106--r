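#' Synthetic coding-matrix generator
#'
#' Generates a policies x sub-variables binary matrix with the
#' statistical structure the PMC pipeline assumes: independent columns
#' are Bernoulli(p), and configured mutually exclusive blocks get
#' exactly one 1 per row, drawn from categorical weights. The defaults
#' mirror the packaged study corpus: 165 policies, satisfaction
#' probability 0.5 on free columns, and the four issuer flags
#' (X3_1..X3_4) as an exclusive block with weights (1, 0, 0, 0) — every
#' policy issued by the state, which pins the issuing-institution
#' first-level value at 0.25.
#'
#' @param n_policies number of synthetic policies.
#' @param probabilities Bernoulli satisfaction probability for columns
#'   outside exclusive blocks: a single number or a named vector by
#'   sub-variable id (unnamed entries default 0.5).
#' @param exclusive_blocks list of `list(ids =, weights =)` groups;
#'   weights must sum to 1. Use `list()` for none.
#' @param seed integer seed; all randomness derives from it.
#' @return `matrix_config()`: a config list. `generate_matrix()`: list
#'   with `coding` (a [pmc_coding][coding_matrix]) and `truth` (the
#'   per-column probabilities and per-row block selections actually
#'   used).
#' @examples
#' cfg <- matrix_config(n_policies = 20, seed = 7)
#' gen <- generate_matrix(cfg, default_schema())
#' all(pmc(gen$coding)$first_level[, "X3"] == 0.25)
#' @export
matrix_config <- function(n_policies = 165L,
                          probabilities = 0.5,
                          exclusive_blocks = list(
                            list(ids = paste0("X3_", 1:4),
                                 weights = c(1, 0, 0, 0))),
                          seed = 1L) {
  if (n_policies < 1L) stop("n_policies must be positive", call. = FALSE)
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (b in exclusive_blocks) {
    if (abs(sum(b$weights) - 1) > 1e-9) {
      stop("exclusive-block weights must sum to 1", call. = FALSE)
    }
    if (length(b$weights) != length(b$ids)) {
      stop("exclusive block: ids and weights differ in length", call. = FALSE)
    }
  }
  list(n_policies = as.integer(n_policies), probabilities = probabilities,
       exclusive_blocks = exclusive_blocks, seed = as.integer(seed))
}

#' @rdname matrix_config
#' @param config a config from `matrix_config()`.
#' @param schema the [pmc_schema][load_schema] to generate against.
#' @export
generate_matrix <- function(config, schema = default_schema()) {
  stopifnot(inherits(schema, "pmc_schema"))
  sid <- subvariable_ids(schema)
  block_ids <- unlist(lapply(config$exclusive_blocks, `[[`, "ids"))
  if (anyDuplicated(block_ids)) {
    stop("exclusive blocks overlap", call. = FALSE)
  }
  unknown <- setdiff(block_ids, sid)
  if (length(unknown)) {
    stop(sprintf("exclusive block references unknown sub-variable '%s'",
                 unknown[1L]), call. = FALSE)
  }
  free <- setdiff(sid, block_ids)
  p <- rep(0.5, length(free))
  names(p) <- free
  if (is.null(names(config$probabilities))) {
    p[] <- config$probabilities
  } else {
    known <- intersect(names(config$probabilities), free)
    p[known] <- config$probabilities[known]
  }
  n <- config$n_policies
  values <- matrix(0L, nrow = n, ncol = length(sid),
                   dimnames = list(NULL, sid))
  block_draws <- list()
  with_seed(config$seed, {
    for (id in free) {
      values[, id] <- stats::rbinom(n, 1L, p[id])
    }
    for (b in config$exclusive_blocks) {
      pick <- sample.int(length(b$ids), n, replace = TRUE, prob = b$weights)
      for (j in seq_along(b$ids)) values[pick == j, b$ids[j]] <- 1L
      block_draws[[paste(b$ids, collapse = "+")]] <- b$ids[pick]
    }
  })
  policies <- data.frame(policy_id = sprintf("S%03d", seq_len(n)),
                         stringsAsFactors = FALSE)
  list(coding = coding_matrix(policies, values, schema),
       truth = list(probabilities = p, block_draws = block_draws,
                    config = config))
}

#' Synthetic token-corpus generator
#'
#' Generates whitespace-tokenizable documents over a weighted
#' vocabulary, optionally planting term pairs that co-occur in a
#' document with a configured probability. Token draws are multinomial
#' with probability proportional to the vocabulary weights. For each
#' planted pair and document, all naturally drawn occurrences of the
#' pair's terms are first resampled away, then with the configured
#' probability both terms are written into two distinct random
#' positions — so the per-document co-occurrence probability is exactly
#' as configured.
#'
#' @param vocabulary named numeric vector: term -> positive occurrence
#'   weight.
#' @param n_documents,tokens_per_document corpus dimensions.
#' @param planted_pairs list of `list(terms = c(a, b), prob = p)`.
#' @param seed integer seed.
#' @return `corpus_config()`: a config list. `generate_corpus()`: list
#'   with `texts` (named character vector, tokens joined by spaces with
#'   a final period), `tokens` (the pre-tokenized streams), and `truth`
#'   (planted co-occurrence indicators per document and the config).
#' @examples
#' cfg <- corpus_config(vocabulary = c(drug = 4, review = 2, tcm = 1),
#'                      n_documents = 3, tokens_per_document = 10, seed = 2)
#' gen <- generate_corpus(cfg)
#' lengths(gen$tokens)
#' @export
corpus_config <- function(vocabulary,
                          n_documents = 50L, tokens_per_document = 200L,
                          planted_pairs = list(), seed = 1L) {
  if (missing(vocabulary) || !length(vocabulary)) {
    stop("vocabulary must be non-empty", call. = FALSE)
  }
  if (is.null(names(vocabulary)) || any(!nzchar(names(vocabulary)))) {
    stop("vocabulary must be a named weight vector", call. = FALSE)
  }
  if (any(vocabulary <= 0)) stop("vocabulary weights must be positive",
                                 call. = FALSE)
  for (pp in planted_pairs) {
    if (length(pp$terms) != 2L) {
      stop("each planted pair needs exactly two terms", call. = FALSE)
    }
    if (pp$prob < 0 || pp$prob > 1) {
      stop("planted-pair probability must lie in [0, 1]", call. = FALSE)
    }
  }
  list(vocabulary = vocabulary, n_documents = as.integer(n_documents),
       tokens_per_document = as.integer(tokens_per_document),
       planted_pairs = planted_pairs, seed = as.integer(seed))
}

#' @rdname corpus_config
#' @param config a config from `corpus_config()`.
#' @export
generate_corpus <- function(config) {
  vocab <- config$vocabulary
  terms <- names(vocab)
  pair_terms <- unique(unlist(lapply(config$planted_pairs, `[[`, "terms")))
  filler <- setdiff(terms, pair_terms)
  if (length(config$planted_pairs) && !length(filler)) {
    stop("vocabulary must contain at least one term outside the planted pairs",
         call. = FALSE)
  }
  n <- config$n_documents
  m <- config$tokens_per_document
  planted <- matrix(FALSE, nrow = n, ncol = length(config$planted_pairs))
  tokens <- vector("list", n)
  with_seed(config$seed, {
    for (d in seq_len(n)) {
      tok <- sample(terms, m, replace = TRUE, prob = vocab)
      for (q in seq_along(config$planted_pairs)) {
        pp <- config$planted_pairs[[q]]
        hit <- tok %in% pp$terms
        if (any(hit)) {
          tok[hit] <- sample(filler, sum(hit), replace = TRUE,
                             prob = vocab[filler])
        }
        if (stats::runif(1L) < pp$prob) {
          pos <- sample.int(m, 2L)
          tok[pos] <- pp$terms
          planted[d, q] <- TRUE
        }
      }
      tokens[[d]] <- tok
    }
  })
  names(tokens) <- sprintf("doc%03d", seq_len(n))
  texts <- vapply(tokens, function(t) paste0(paste(t, collapse = " "), "."),
                  character(1L))
  list(texts = texts, tokens = tokens,
       truth = list(planted = planted, config = config))
}

#' The packaged published score table
#'
#' The complete first-level score table of the 165-policy Chinese
#' traditional-medicine drug registration corpus, transcribed verbatim
#' as printed (values to two decimals, including its typographical
#' quirks — see [table4_validation()]), plus the printed per-column
#' average row.
#'
#' @return `table4_scores()`: data.frame of 165 rows with columns
#'   `policy`, `X1`..`X9`, `pmc`, and attribute `average_row` (the
#'   printed ten-value average row, named).
#' @examples
#' tab <- table4_scores()
#' nrow(tab)
#' attr(tab, "average_row")[["X3"]]
#' @export
table4_scores <- function() {
  path <- system.file("extdata", "table4_scores.csv",
                      package = "pmcindex", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  avg <- df[df$policy == "Average value", ]
  df <- df[df$policy != "Average value", ]
  rownames(df) <- NULL
  a <- as.numeric(avg[1L, -1L])
  names(a) <- names(avg)[-1L]
  attr(df, "average_row") <- a
  df
}

#' Validate the packaged score table against the framework
#'
#' Reports (never corrects) two kinds of printed quirks: rows whose
#' printed PMC differs from the report-parity sum of the printed
#' first-level values by more than a tolerance, and cells whose printed
#' value is not expressible as a rounded fraction j/T for the
#' framework's sub-variable count T of that primary (e.g. a printed
#' 0.67 under a 4-sub-variable primary).
#'
#' @param fixture the data.frame from [table4_scores()].
#' @param schema the framework to check counts against.
#' @param tol parity tolerance on the printed PMC (default 0.01).
#' @return List with data.frames `parity_failures` (policy, printed,
#'   recomputed) and `nonrepresentable` (policy, primary, value).
#' @export
table4_validation <- function(fixture = table4_scores(),
                              schema = default_schema(), tol = 0.01) {
  pid <- primary_ids(schema)
  cnt <- subvariable_counts(schema)
  fl <- as.matrix(fixture[pid])
  recomputed <- apply(fl, 1L, pmc_index, rounding = "report-parity")
  off <- abs(recomputed - fixture$pmc) > tol + 1e-9
  parity <- data.frame(policy = fixture$policy[off],
                       printed = fixture$pmc[off],
                       recomputed = recomputed[off],
                       stringsAsFactors = FALSE)
  nonrep <- do.call(rbind, lapply(pid, function(p) {
    ok_vals <- round_half_up((0:cnt[[p]]) / cnt[[p]], 2L)
    bad <- which(!fixture[[p]] %in% ok_vals)
    if (!length(bad)) return(NULL)
    data.frame(policy = fixture$policy[bad], primary = p,
               value = fixture[[p]][bad], stringsAsFactors = FALSE)
  }))
  if (is.null(nonrep)) {
    nonrep <- data.frame(policy = character(), primary = character(),
                         value = numeric(), stringsAsFactors = FALSE)
  }
  rownames(nonrep) <- NULL
  list(parity_failures = parity, nonrepresentable = nonrep)
}
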