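# Brute-force oracles kept deliberately naive and independent of the package
# implementations they check.

# distinct gap-stripped window sequences at a 0-based start
oracle_window_alleles <- function(seqs, start, len) {
  win <- vapply(seqs, function(s) {
    gsub("-", "", substr(s, start + 1, start + len), fixed = TRUE)
  }, character(1))
  length(unique(win))
}

# multiset tally without hashing tricks: sort then run-length
oracle_dereplicate <- function(seqs) {
  s <- sort(seqs)
  r <- rle(s)
  data.frame(sequence = r$values, abundance = r$lengths, stringsAsFactors = FALSE)
}

# best ungapped local alignment by exhaustive diagonal scan with all
# start/end pairs (O(n^3)), +1/-2 scoring
oracle_local_align <- function(query, subject) {
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  lq <- length(q); ls <- length(s)
  best <- list(score = -Inf)
  for (d in seq(-(lq - 1), ls - 1)) {
    lo_q <- max(1, 1 - d); hi_q <- min(lq, ls - d)
    if (hi_q < lo_q) next
    m <- q[lo_q:hi_q] == s[(lo_q + d):(hi_q + d)]
    v <- ifelse(m, 1, -2)
    n <- length(v)
    cs <- cumsum(v)
    for (a in seq_len(n)) for (b in a:n) {
      sc <- cs[b] - if (a > 1) cs[a - 1] else 0
      if (sc > best$score) {
        alen <- b - a + 1
        best <- list(score = sc,
                     identity = sum(m[a:b]) / alen,
                     coverage = alen / lq)
      }
    }
  }
  best
}

# exact permutation p for Kruskal-Wallis via stats::kruskal.test on every
# distinct group assignment
oracle_kw_exact_p <- function(values, groups) {
  groups <- as.factor(groups)
  sizes <- as.integer(table(groups))
  N <- sum(sizes)
  h_obs <- suppressWarnings(stats::kruskal.test(values, groups)$statistic)
  assignments <- list()
  recurse <- function(remaining, gi, acc) {
    if (gi > length(sizes)) {
      assignments[[length(assignments) + 1]] <<- acc
      return(invisible())
    }
    for (p in utils::combn(remaining, sizes[gi], simplify = FALSE)) {
      acc2 <- acc; acc2[p] <- gi
      recurse(setdiff(remaining, p), gi + 1, acc2)
    }
  }
  recurse(seq_len(N), 1, integer(N))
  hs <- vapply(assignments, function(a) {
    suppressWarnings(stats::kruskal.test(values, as.factor(a))$statistic)
  }, numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# reciprocal best hits from a full score matrix computed independently
oracle_bbh <- function(score_ab) {
  pairs <- list()
  for (a in rownames(score_ab)) {
    sa <- score_ab[a, ]
    if (all(!is.finite(sa))) next
    b <- colnames(score_ab)[order(-sa, colnames(score_ab))][1]
    sb <- score_ab[, b]
    a_back <- rownames(score_ab)[order(-sb, rownames(score_ab))][1]
    if (a_back == a) pairs[[length(pairs) + 1]] <- c(a = a, b = b)
  }
  do.call(rbind, pairs)
}

tiny_panel <- function(n = 4, allele_length = 40, seed = 7, ...) {
  simulate_panel(n_strains = n, allele_length = allele_length, seed = seed, ...)
}

phred_string <- function(q, n) {
  paste(rep(intToUtf8(q + 33), n), collapse = "")
}
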