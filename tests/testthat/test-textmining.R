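test_that("tokenisation strategies segment deterministically", {
  corp <- tokenize_corpus(c(d1 = "drug registration of drug"),
                          stopwords = "of")
  expect_equal(unlist(corp$documents$d1), c("drug", "registration", "drug"))

  empty <- tokenize_corpus(c(d1 = ""))
  expect_equal(length(empty$documents$d1), 0L)

  bigrams <- tokenize_corpus(c(d = "中药注册"), segmenter = "ngram")
  expect_equal(unlist(bigrams$documents$d), c("中药", "药注", "注册"))

  fmm <- tokenize_corpus(c(d = "中药注册管理办法"), segmenter = "dictionary",
                         dictionary = c("中药", "注册", "管理办法", "管理"))
  # longest dictionary match wins at each position
  expect_equal(unlist(fmm$documents$d), c("中药", "注册", "管理办法"))
  fmm2 <- tokenize_corpus(c(d = "新药GMP认证"), segmenter = "dictionary",
                          dictionary = c("新药", "认证"))
  expect_equal(unlist(fmm2$documents$d), c("新药", "GMP", "认证"))
  expect_error(tokenize_corpus(c(d = "x"), segmenter = "dictionary"),
               "dictionary")

  # sentences split on Chinese and Latin terminal punctuation
  s <- tokenize_corpus(c(d = "drug review. clinical trial! 注册 审批？"))
  expect_equal(length(s$documents$d), 3L)
})

test_that("no stopword survives into tokens, frequencies, or networks", {
  sw <- c("of", "the", "的")
  corp <- tokenize_corpus(c(d1 = "the review of the drug 的 approval",
                            d2 = "the drug of review"), stopwords = sw)
  expect_false(any(unlist(corp$documents) %in% sw))
  tf <- term_frequencies(corp)
  expect_false(any(tf$term %in% sw))
  g <- cooccurrence_network(corp, min_edge_weight = 1L)
  expect_false(any(igraph::V(g)$name %in% sw))
})

test_that("frequency table counts, document frequencies and tie order", {
  corp <- tokenize_corpus(c(d = "drug registration of drug"),
                          stopwords = "of")
  tf <- term_frequencies(corp, top_k = 2L)
  expect_equal(tf$term, c("drug", "registration"))
  expect_equal(tf$count, c(2L, 1L))
  expect_equal(tf$doc_freq, c(1L, 1L))
  expect_equal(attr(tf, "total_tokens"), 3L)

  two <- tokenize_corpus(c(a = "clinical review", b = "clinical trial"))
  tf2 <- term_frequencies(two)
  expect_equal(tf2$doc_freq[tf2$term == "clinical"], 2L)
  # equal counts break ties lexicographically
  expect_equal(tf2$term, c("clinical", "review", "trial"))
  # token conservation
  expect_equal(attr(tf2, "total_tokens"),
               sum(lengths(lapply(two$documents, unlist))))

  expect_equal(nrow(term_frequencies(tokenize_corpus(c(d = "")))), 0L)
})

test_that("co-occurrence weights follow per-window pair counting", {
  one <- tokenize_corpus(c(d = "drug registration."))
  g <- cooccurrence_network(one, min_edge_weight = 1L)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 1L)
  expect_setequal(igraph::V(g)$name, c("drug", "registration"))

  # repeats inside one window still count once
  rep4 <- tokenize_corpus(c(d = "a b a b"))
  g2 <- cooccurrence_network(rep4, window = "document",
                             min_edge_weight = 1L)
  expect_equal(igraph::E(g2)$weight, 1L)

  expect_error(cooccurrence_network(one, window = "sliding", k = 1L),
               "at least 2")
})

test_that("network weights equal the exhaustive pair-counting oracle", {
  set.seed(31)
  vocab <- letters[1:6]
  for (rep in 1:6) {
    n_docs <- sample(1:5, 1L)
    texts <- vapply(seq_len(n_docs), function(i) {
      n_tok <- sample(1:20, 1L)
      paste(sample(vocab, n_tok, replace = TRUE), collapse = " ")
    }, character(1L))
    names(texts) <- paste0("d", seq_len(n_docs))
    for (win in c("sentence", "document")) {
      corp <- tokenize_corpus(texts)
      g <- cooccurrence_network(corp, window = win, min_edge_weight = 1L)
      windows <- if (win == "document") {
        lapply(corp$documents, unlist)
      } else {
        unlist(corp$documents, recursive = FALSE)
      }
      expected <- oracle_cooccurrence(windows)
      expect_equal(igraph::ecount(g), length(expected))
      for (key in names(expected)) {
        ends <- strsplit(key, "|", fixed = TRUE)[[1L]]
        eid <- igraph::get_edge_ids(g, ends)
        expect_gt(eid, 0)
        expect_equal(igraph::E(g)$weight[eid], expected[[key]])
        # symmetry under argument exchange
        expect_equal(igraph::get_edge_ids(g, rev(ends)), eid)
      }
    }
  }
})

test_that("sliding windows and edge filtering behave as documented", {
  corp <- tokenize_corpus(c(d = "a b c d e"))
  g <- cooccurrence_network(corp, window = "sliding", k = 2L,
                            min_edge_weight = 1L)
  # adjacent pairs only, each once
  expect_equal(igraph::ecount(g), 4L)
  expect_true(all(igraph::E(g)$weight == 1L))

  multi <- tokenize_corpus(c(a = "x y. x y. x z."))
  g1 <- cooccurrence_network(multi, min_edge_weight = 1L)
  g2 <- cooccurrence_network(multi, min_edge_weight = 2L)
  # raising the threshold never adds edges, and drops isolated nodes
  expect_lte(igraph::ecount(g2), igraph::ecount(g1))
  expect_setequal(igraph::V(g2)$name, c("x", "y"))
  expect_equal(igraph::E(g2)$weight, 2L)
  # no self-loops anywhere
  expect_false(any(igraph::which_loop(g1)))
})

test_that("centrality reports degree and weighted degree", {
  star <- tokenize_corpus(c(a = "hub l1", b = "hub l2", c = "hub l3"))
  g <- cooccurrence_network(star, min_edge_weight = 1L)
  cen <- network_centrality(g)
  expect_equal(cen$degree[cen$term == "hub"], 3L)
  expect_true(all(cen$degree[cen$term != "hub"] == 1L))
  expect_equal(cen$weighted_degree[cen$term == "hub"], 3)
  expect_error(network_centrality(igraph::make_empty_graph(0)), "empty")

  # degrees equal brute-force adjacency counting on a random graph
  set.seed(5)
  corp <- tokenize_corpus(c(d = paste(sample(letters[1:5], 40,
                                             replace = TRUE),
                                      collapse = " ")))
  g2 <- cooccurrence_network(corp, window = "sliding", k = 3L,
                             min_edge_weight = 1L)
  cen2 <- network_centrality(g2)
  el <- igraph::as_data_frame(g2, what = "edges")
  for (i in seq_len(nrow(cen2))) {
    inc <- el$from == cen2$term[i] | el$to == cen2$term[i]
    expect_equal(cen2$degree[i], sum(inc))
    expect_equal(cen2$weighted_degree[i], sum(el$weight[inc]))
  }
})

test_that("networks export to GraphML and edge-list CSV", {
  corp <- tokenize_corpus(c(d = "drug review. drug review. drug trial."))
  g <- cooccurrence_network(corp, min_edge_weight = 1L)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_network(g, csv, format = "edgelist")
  el <- utils::read.csv(csv)
  expect_equal(nrow(el), igraph::ecount(g))
  expect_setequal(names(el), c("from", "to", "weight"))
})

test_that("raw texts load from a directory or a two-column CSV", {
  d <- withr::local_tempdir()
  writeLines("drug registration", file.path(d, "P1.txt"))
  writeLines("clinical trial", file.path(d, "P2.txt"))
  tx <- read_texts(d)
  expect_equal(names(tx), c("P1", "P2"))
  expect_equal(unname(tx[1L]), "drug registration")

  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(policy_id = "P9", text = "drug law"), f,
                   row.names = FALSE)
  tx2 <- read_texts(f)
  expect_equal(tx2, c(P9 = "drug law"))
  expect_error(read_texts(file.path(d, "nope")), "no such")
})

test_that("the packaged stopword list loads and is non-trivial", {
  sw <- default_stopwords()
  expect_true(length(sw) > 20L)
  expect_true("的" %in% sw && "the" %in% sw)
  expect_false(any(grepl("^#", sw)))
})
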