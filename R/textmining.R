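#' Tokenize a policy corpus
#'
#' Splits each document into sentences (on Chinese and Latin
#' sentence-final punctuation: 。！？.!?) and segments each sentence
#' into tokens with a pluggable strategy:
#'
#' * `"whitespace"` — split on runs of whitespace; for
#'   whitespace-delimited (e.g. synthetic or Latin-script) text.
#' * `"ngram"` — overlapping character n-grams (default n = 2) of each
#'   non-space run; a dictionary-free baseline for unsegmented Chinese.
#' * `"dictionary"` — forward maximum matching against a user-supplied
#'   term dictionary (longest dictionary term wins at each position);
#'   characters not covered by the dictionary become single-character
#'   tokens. Latin/digit runs are kept whole.
#'
#' Stopwords are removed after segmentation, so a stopword never
#' appears in any downstream frequency table or network.
#'
#' @param texts named character vector/list, policy_id -> document text.
#' @param segmenter one of `"whitespace"`, `"ngram"`, `"dictionary"`.
#' @param stopwords character vector of terms to drop
#'   (see [default_stopwords()]).
#' @param dictionary character vector of terms for the dictionary
#'   strategy.
#' @param n n-gram width for the ngram strategy.
#' @return A `pmc_corpus`: list with `documents` (per document, a list
#'   of sentence token vectors), `segmenter`, `stopwords`.
#' @examples
#' corp <- tokenize_corpus(c(d1 = "drug registration of drug"),
#'                         stopwords = "of")
#' term_frequencies(corp)
#' @export
tokenize_corpus <- function(texts,
                            segmenter = c("whitespace", "ngram", "dictionary"),
                            stopwords = character(), dictionary = NULL,
                            n = 2L) {
  segmenter <- match.arg(segmenter)
  texts <- unlist(as.list(texts))
  if (is.null(names(texts))) names(texts) <- paste0("D", seq_along(texts))
  if (segmenter == "dictionary" && (is.null(dictionary) || !length(dictionary))) {
    stop("the dictionary segmenter needs a non-empty `dictionary`",
         call. = FALSE)
  }
  seg <- switch(segmenter,
                whitespace = function(s) {
                  t <- strsplit(s, "[[:space:]]+")[[1L]]
                  t[nzchar(t)]
                },
                ngram = function(s) segment_ngram(s, n),
                dictionary = function(s) segment_fmm(s, dictionary))
  documents <- lapply(texts, function(tx) {
    sentences <- strsplit(tx, "[。！？.!?]+")[[1L]]
    sentences <- trimws(sentences)
    sentences <- sentences[nzchar(sentences)]
    toks <- lapply(sentences, function(s) {
      t <- seg(s)
      t[!t %in% stopwords]
    })
    toks[lengths(toks) > 0L]
  })
  structure(list(documents = documents, segmenter = segmenter,
                 stopwords = stopwords),
            class = "pmc_corpus")
}

# overlapping character n-grams over non-space, non-punctuation runs
segment_ngram <- function(s, n) {
  runs <- strsplit(s, "[[:space:][:punct:]]+")[[1L]]
  runs <- runs[nzchar(runs)]
  unlist(lapply(runs, function(r) {
    ch <- strsplit(r, "")[[1L]]
    if (length(ch) <= n) return(paste(ch, collapse = ""))
    vapply(seq_len(length(ch) - n + 1L), function(i) {
      paste(ch[i:(i + n - 1L)], collapse = "")
    }, character(1L))
  }), use.names = FALSE)
}

# forward maximum matching: at each position take the longest
# dictionary term; otherwise emit one character (whole Latin/digit runs)
segment_fmm <- function(s, dictionary) {
  s <- gsub("[[:space:]]+", " ", s)
  maxlen <- max(nchar(dictionary))
  ch <- strsplit(s, "")[[1L]]
  out <- character(0L)
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == " ") { i <- i + 1L; next }
    hit <- ""
    for (l in seq(min(maxlen, length(ch) - i + 1L), 1L)) {
      cand <- paste(ch[i:(i + l - 1L)], collapse = "")
      if (cand %in% dictionary) { hit <- cand; break }
    }
    if (nzchar(hit)) {
      out <- c(out, hit)
      i <- i + nchar(hit)
    } else if (grepl("[A-Za-z0-9]", ch[i])) {
      j <- i
      while (j < length(ch) && grepl("[A-Za-z0-9]", ch[j + 1L])) j <- j + 1L
      out <- c(out, paste(ch[i:j], collapse = ""))
      i <- j + 1L
    } else {
      if (!grepl("[[:punct:]]", ch[i])) out <- c(out, ch[i])
      i <- i + 1L
    }
  }
  out
}

#' The packaged default stopword list
#'
#' Common Chinese and English function words, shipped as an editable
#' plain-text file (`system.file("extdata", "stopwords_default.txt",
#' package = "pmcindex")`). Intended as a starting point, not a
#' canonical list.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  lines <- readLines(system.file("extdata", "stopwords_default.txt",
                                 package = "pmcindex", mustWork = TRUE),
                     encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read raw policy texts
#'
#' Accepts either a directory of UTF-8 plain-text files (one document
#' per file; the file name minus extension is the policy id) or a
#' two-column CSV (`policy_id`, `text`).
#'
#' @param path directory or CSV file.
#' @return Named character vector of document texts.
#' @export
read_texts <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    out <- vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1L))
    names(out) <- tools::file_path_sans_ext(basename(files))
    out
  } else if (file.exists(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    stats::setNames(as.character(df$text), df$policy_id)
  } else {
    stop(sprintf("no such file or directory: '%s'", path), call. = FALSE)
  }
}

doc_tokens <- function(corpus) {
  lapply(corpus$documents, function(d) unlist(d, use.names = FALSE))
}

#' High-frequency term table
#'
#' Ranks terms by total corpus count (ties broken lexicographically)
#' and reports each term's document frequency — the number of documents
#' it appears in at least once.
#'
#' @param corpus a `pmc_corpus` from [tokenize_corpus()].
#' @param top_k how many terms to keep (default 50).
#' @return A data.frame (term, count, doc_freq) with attribute
#'   `total_tokens`; empty for an empty corpus.
#' @export
term_frequencies <- function(corpus, top_k = 50L) {
  stopifnot(inherits(corpus, "pmc_corpus"), top_k >= 1L)
  toks <- doc_tokens(corpus)
  all_tokens <- unlist(toks, use.names = FALSE)
  if (!length(all_tokens)) {
    out <- data.frame(term = character(), count = integer(),
                      doc_freq = integer(), stringsAsFactors = FALSE)
    attr(out, "total_tokens") <- 0L
    return(out)
  }
  cnt <- table(all_tokens)
  dfq <- table(unlist(lapply(toks, unique), use.names = FALSE))
  terms <- names(cnt)
  ord <- order(-as.integer(cnt), terms)
  terms <- terms[ord][seq_len(min(top_k, length(terms)))]
  out <- data.frame(term = terms,
                    count = as.integer(cnt[terms]),
                    doc_freq = as.integer(dfq[terms]),
                    stringsAsFactors = FALSE)
  attr(out, "total_tokens") <- length(all_tokens)
  out
}

#' Co-occurrence semantic network
#'
#' Builds the undirected weighted term graph behind a network semantic
#' map: nodes are terms (with corpus frequency as a vertex attribute),
#' and the weight of edge \{a, b\} is the number of windows in which a
#' and b both occur — counted once per window however often either term
#' repeats inside it. Windows are sentences (default), whole documents,
#' or sliding spans of `k` consecutive tokens (step 1; a document
#' shorter than `k` forms one window). Edges below `min_edge_weight`
#' and the nodes they leave isolated are dropped.
#'
#' @param corpus a `pmc_corpus`.
#' @param window `"sentence"`, `"document"` or `"sliding"`.
#' @param k sliding-window width (tokens), at least 2.
#' @param min_edge_weight minimum co-occurrence count to keep an edge.
#' @return An [igraph][igraph::graph_from_data_frame] graph with vertex
#'   attribute `freq` and edge attribute `weight`.
#' @examples
#' corp <- tokenize_corpus(c(d = "drug registration. drug approval."))
#' g <- cooccurrence_network(corp, min_edge_weight = 1)
#' igraph::E(g)$weight
#' @export
cooccurrence_network <- function(corpus,
                                 window = c("sentence", "document", "sliding"),
                                 k = 5L, min_edge_weight = 2L) {
  stopifnot(inherits(corpus, "pmc_corpus"), min_edge_weight >= 1L)
  window <- match.arg(window)
  if (window == "sliding" && k < 2L) {
    stop("sliding window width must be at least 2", call. = FALSE)
  }
  windows <- switch(window,
    sentence = unlist(lapply(corpus$documents, identity), recursive = FALSE,
                      use.names = FALSE),
    document = doc_tokens(corpus),
    sliding = unlist(lapply(doc_tokens(corpus), function(t) {
      if (length(t) <= k) return(list(t))
      lapply(seq_len(length(t) - k + 1L), function(i) t[i:(i + k - 1L)])
    }), recursive = FALSE, use.names = FALSE))
  pair_env <- new.env(hash = TRUE, parent = emptyenv())
  for (w in windows) {
    u <- sort(unique(w))
    if (length(u) < 2L) next
    cmb <- utils::combn(u, 2L)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1L, j], cmb[2L, j], sep = "\x1f")
      pair_env[[key]] <- (pair_env[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(pair_env)
  weights <- vapply(keys, function(k2) pair_env[[k2]], integer(1L))
  keep <- weights >= min_edge_weight
  keys <- keys[keep]; weights <- weights[keep]
  if (!length(keys)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  ends <- do.call(rbind, strsplit(keys, "\x1f", fixed = TRUE))
  edges <- data.frame(from = ends[, 1L], to = ends[, 2L], weight = weights,
                      stringsAsFactors = FALSE)
  freq <- table(unlist(doc_tokens(corpus), use.names = FALSE))
  verts <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = verts, freq = as.integer(freq[verts]),
                          stringsAsFactors = FALSE))
  g
}

#' Degree and weighted degree of network terms
#'
#' Quantifies which terms sit at the core of the semantic map (high
#' degree / weighted degree) versus its periphery.
#'
#' @param network an igraph graph from [cooccurrence_network()].
#' @return A data.frame (term, degree, weighted_degree) sorted by
#'   weighted degree descending, ties lexicographic.
#' @export
network_centrality <- function(network) {
  if (igraph::vcount(network) == 0L) {
    stop("empty network", call. = FALSE)
  }
  deg <- igraph::degree(network)
  wdeg <- igraph::strength(network, weights = igraph::E(network)$weight)
  out <- data.frame(term = names(deg), degree = as.integer(deg),
                    weighted_degree = as.numeric(wdeg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weighted_degree, out$term), ]
  rownames(out) <- NULL
  out
}

#' Export a co-occurrence network
#'
#' Writes the graph either as GraphML (for network viewers, which own
#' the layout) or as a weighted edge-list CSV (from, to, weight).
#'
#' @param network an igraph graph.
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_network <- function(network, path,
                          format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(network, what = "edges")
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
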