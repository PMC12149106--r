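# Shared fixtures and independent oracles, all built in code.

toy_schema_yaml <- "
name: toy
primaries:
  - id: A
    label: first
    subvariables:
      - {id: A_1, label: a1}
      - {id: A_2, label: a2}
  - id: B
    label: second
    subvariables:
      - {id: B_1, label: b1}
      - {id: B_2, label: b2}
      - {id: B_3, label: b3}
"

toy_schema <- function() load_schema(toy_schema_yaml)

# random schema with n_prim primaries of 1..max_sub sub-variables each
random_schema <- function(n_prim, max_sub) {
  prim <- paste(vapply(seq_len(n_prim), function(i) {
    subs <- paste(vapply(seq_len(sample.int(max_sub, 1L)), function(j) {
      sprintf("      - {id: V%d_%d}", i, j)
    }, character(1L)), collapse = "\n")
    sprintf("  - id: V%d\n    subvariables:\n%s", i, subs)
  }, character(1L)), collapse = "\n")
  load_schema(paste0("name: random\nprimaries:\n", prim))
}

# brute-force PMC scoring: enumerate cells directly, no matrix algebra
oracle_scores <- function(coding, rounding = "report-parity") {
  schema <- coding$schema
  vapply(seq_len(nrow(coding$values)), function(r) {
    fl <- vapply(schema$primaries, function(p) {
      tot <- 0
      for (s in p$subvariables) tot <- tot + coding$values[r, s$id]
      tot / length(p$subvariables)
    }, numeric(1L))
    if (rounding == "report-parity") {
      sum(vapply(fl, function(v) floor(v * 100 + 0.5 + 1e-9) / 100,
                 numeric(1L)))
    } else {
      sum(fl)
    }
  }, numeric(1L))
}

# exhaustive pair-counting oracle over explicit windows
oracle_cooccurrence <- function(windows) {
  counts <- list()
  for (w in windows) {
    u <- sort(unique(w))
    if (length(u) < 2L) next
    for (i in seq_len(length(u) - 1L)) {
      for (j in seq((i + 1L), length(u))) {
        key <- paste(u[i], u[j], sep = "|")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

table4_first_level <- function(tab = table4_scores()) {
  as.matrix(tab[paste0("X", 1:9)])
}
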