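test_that("Kruskal-Wallis matches stats::kruskal.test and exact enumeration", {
  set.seed(401)
  # identical multisets in two groups: H = 0, p = 1
  kw0 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  # H and chi-square p agree with stats::kruskal.test, with and without ties
  for (i in 1:10) {
    n <- sample(6:15, 1)
    v <- sample(1:8, n, replace = TRUE) # plenty of ties
    g <- sample(letters[1:3], n, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(v)) == 1) next
    ours <- kruskal_wallis(v, g)
    ref <- stats::kruskal.test(v, as.factor(g))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }

  # exact permutation p equals the brute-force enumeration oracle
  cases <- list(list(v = c(1.2, 3.4, 0.5, 2.2, 5.1, 4.4), g = rep(c("a", "b"), each = 3)),
                list(v = c(1, 1, 2, 3, 3, 4, 7), g = c("a", "a", "b", "b", "b", "c", "c")),
                list(v = rnorm(8), g = rep(c("a", "b"), each = 4)))
  for (cs in cases) {
    ours <- kruskal_wallis(cs$v, cs$g, exact = "always")
    expect_equal(ours$p_exact, oracle_kw_exact_p(cs$v, cs$g), tolerance = 1e-12)
  }

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two groups")
  expect_error(kruskal_wallis(c(1, 2), c("a", "b")), "three observations")
})

test_that("Dunn z and p match direct formula evaluation on a hand-sized example", {
  v <- c(2, 4, 6, 1, 3, 5, 10, 12, 14)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_posthoc(v, g)
  # independent arithmetic: no ties, N = 9
  r <- rank(v); N <- 9
  rb <- tapply(r, g, mean)
  se <- sqrt((N * (N + 1) / 12) * (1 / 3 + 1 / 3))
  z_ab <- (rb[["a"]] - rb[["b"]]) / se
  z_ac <- (rb[["a"]] - rb[["c"]]) / se
  p_ac <- min(1, 2 * pnorm(-abs(z_ac)) * 3)
  row_ab <- d$pairs[d$pairs$group1 == "a" & d$pairs$group2 == "b", ]
  row_ac <- d$pairs[d$pairs$group1 == "a" & d$pairs$group2 == "c", ]
  expect_equal(row_ab$z, z_ab, tolerance = 1e-12)
  expect_equal(row_ac$p_adjusted, p_ac, tolerance = 1e-12)
  # Bonferroni never reduces p
  expect_true(all(d$pairs$p_adjusted >= d$pairs$p_value - 1e-15))
})

test_that("compact letters share a letter iff not significantly different", {
  # three identical groups: all p = 1, single shared letter
  d0 <- dunn_posthoc(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(d0$pairs$p_adjusted == 1))
  expect_equal(unique(d0$letters$letters), "a")

  # clearly separated groups get distinct letters
  set.seed(402)
  v <- c(rnorm(8, 0), rnorm(8, 50), rnorm(8, 100))
  g <- rep(c("lo", "mid", "hi"), each = 8)
  d1 <- dunn_posthoc(v, g)
  sig <- d1$pairs$p_adjusted < 0.05
  share <- function(x, y) {
    lx <- d1$letters$letters[d1$letters$group == x]
    ly <- d1$letters$letters[d1$letters$group == y]
    any(strsplit(lx, "")[[1]] %in% strsplit(ly, "")[[1]])
  }
  for (k in seq_len(nrow(d1$pairs))) {
    expect_equal(share(d1$pairs$group1[k], d1$pairs$group2[k]), !sig[k])
  }
})

test_that("species pooling stacks strain-by-cultivar observations", {
  summ <- tidyr::expand_grid(host_genotype = c("K", "I", "A"),
                             strain_id = sprintf("s%02d", 1:13)) |>
    dplyr::mutate(epc_mean = runif(dplyr::n()))
  mp <- c(K = "pea", I = "pea", A = "lentil")
  pooled <- pool_species(summ, mp)
  expect_equal(sum(pooled$host_species == "pea"), 26) # 13 strains x 2 cultivars
  expect_equal(sum(pooled$host_species == "lentil"), 13)
  # pooled medians match direct medians of the stacked vector
  expect_equal(median(pooled$epc[pooled$host_species == "pea"]),
               median(summ$epc_mean[summ$host_genotype %in% c("K", "I")]))
  # single cultivar: pooling is identity
  one <- pool_species(summ[summ$host_genotype == "A", ], mp)
  expect_equal(one$epc, summ$epc_mean[summ$host_genotype == "A"])
  expect_error(pool_species(summ, c(K = "pea")), "unmapped")
})

test_that("strain ranking is stable and tie-broken by reads then label", {
  summ <- tibble::tibble(host_genotype = "H",
                         strain_id = c("s3", "s1", "s2", "s4"),
                         epc_mean = c(5, 5, 9, 1))
  ct <- tibble::tibble(sample_id = "a", strain_id = c("s1", "s2", "s3", "s4"),
                       count = c(100L, 50L, 10L, 5L))
  r <- rank_strains(summ, "H", ct)
  expect_equal(r$strain_id, c("s2", "s1", "s3", "s4")) # tie 5/5 -> s1 has more reads
  r2 <- rank_strains(summ[c(2, 1, 4, 3), ], "H", ct)
  expect_equal(r2$strain_id, r$strain_id)
  expect_error(rank_strains(summ, "nope"), "not present")
})

test_that("gene contrast finds exactly the perfectly separating genes", {
  strains <- sprintf("s%02d", 1:12)
  ranked <- strains # already in descending EPC order
  pm <- matrix(FALSE, 12, 4,
               dimnames = list(strains, c("top_gene", "bottom_gene", "const", "mixed")))
  pm[1:5, "top_gene"] <- TRUE            # present in all top-5, absent below
  pm[8:12, "bottom_gene"] <- TRUE        # reverse direction
  pm[, "const"] <- TRUE
  pm[c(1, 3, 8), "mixed"] <- TRUE
  cand <- contrast_genes(ranked, pm, k_top = 5, k_bottom = 5)
  expect_setequal(cand$gene_id, c("top_gene", "bottom_gene"))
  expect_equal(cand$direction[cand$gene_id == "top_gene"], "present_in_top")
  expect_equal(cand$direction[cand$gene_id == "bottom_gene"], "absent_in_top")

  # restricted comparison: ranking filtered to a subset before top/bottom
  sub <- strains[c(1:3, 10:12)]
  cand_sub <- contrast_genes(ranked, pm, k_top = 3, k_bottom = 3, restrict_to = sub)
  expect_true("top_gene" %in% cand_sub$gene_id)

  expect_error(contrast_genes(ranked, pm, k_top = 7, k_bottom = 7), "overlap")
})

test_that("barcode collision groups aggregate conservatively in contrast and validation", {
  strains <- sprintf("s%02d", 1:10)
  pm <- matrix(FALSE, 10, 2, dimnames = list(strains, c("clean", "mixedtop")))
  pm[1:4, "clean"] <- TRUE; pm["s05", "clean"] <- TRUE  # s04+s05 both carry
  pm[1:4, "mixedtop"] <- TRUE                            # s05 does not carry
  ranked <- c("s01", "s02", "s03", "s04+s05", "s06", "s07", "s08", "s09+s10")
  cand <- contrast_genes(ranked, pm, k_top = 4, k_bottom = 4)
  # "clean" is present in every top strain (incl. both group members) and
  # absent below; "mixedtop" is ambiguous in the s04+s05 group -> no candidate
  expect_equal(cand$gene_id, "clean")

  epc <- tibble::tibble(host_genotype = "H", strain_id = ranked,
                        epc_mean = c(30, 25, 20, 18, 2, 1.5, 1, 0.5))
  v <- validate_candidates(cand, epc, pm, "H")
  expect_equal(v$n_carrier + v$n_noncarrier, 8L)
  expect_lt(v$p_value, 0.05)
  expect_error(contrast_genes(c(ranked, "zzz"), pm, k_top = 4, k_bottom = 4),
               "missing from presence matrix")
})

test_that("validation flags fixed genes and detects planted effects", {
  set.seed(403)
  strains <- sprintf("s%02d", 1:26)
  epc <- tibble::tibble(host_genotype = "H", strain_id = strains,
                        epc_mean = c(rep(20, 5), runif(21, 0, 2)))
  pm <- matrix(FALSE, 26, 2, dimnames = list(strains, c("gA", "fixed")))
  pm[1:5, "gA"] <- TRUE
  pm[, "fixed"] <- TRUE
  cand <- tibble::tibble(gene_id = c("gA", "fixed"), direction = "present_in_top")
  v <- validate_candidates(cand, epc, pm, "H")
  expect_lt(v$p_value[v$gene_id == "gA"], 0.05)
  expect_true(is.na(v$p_value[v$gene_id == "fixed"]))
  expect_match(v$note[v$gene_id == "fixed"], "fixed")

  # single non-carrier runs with a warning
  pm1 <- matrix(TRUE, 26, 1, dimnames = list(strains, "g1")); pm1[26, 1] <- FALSE
  expect_warning(
    v1 <- validate_candidates(tibble::tibble(gene_id = "g1", direction = "present_in_top"),
                              epc, pm1, "H"),
    "single-member")
  expect_equal(c(v1$n_carrier, v1$n_noncarrier), c(25, 1))
})

test_that("local alignment equals the brute-force oracle on small instances", {
  set.seed(404)
  q <- random_dna(1, 50)
  self <- local_align(q, q)
  expect_equal(self$identity, 1)
  expect_equal(self$coverage, 1)

  # embedded with substitutions: compare against exhaustive O(n^3) oracle
  for (i in 1:5) {
    query <- random_dna(1, 60)
    mutated <- mutate_sequence(query, 0.1)
    subject <- paste0(random_dna(1, 40), mutated, random_dna(1, 40))
    got <- local_align(query, subject)
    oracle <- oracle_local_align(query, subject)
    expect_equal(got$score, oracle$score)
    expect_equal(got$identity, oracle$identity)
    expect_equal(got$coverage, oracle$coverage)
  }

  # unrelated random sequences: no high-identity full-coverage hit
  hit <- local_align(random_dna(1, 500), random_dna(1, 1000))
  expect_false(isTRUE(!is.na(hit$identity) && hit$identity > 0.7 && hit$coverage > 0.7))
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("presence checks use strict 70/70 thresholds and are monotone", {
  set.seed(405)
  gene <- random_dna(1, 300)
  genome <- paste0(random_dna(1, 200), gene, random_dna(1, 200))
  expect_true(check_presence(gene, genome))

  decoy_genome <- paste0(random_dna(1, 200), mutate_sequence(gene, 0.4),
                         random_dna(1, 200))
  expect_false(check_presence(gene, decoy_genome)) # ~60% identity decoy

  # monotone: raising either threshold never converts absent -> present
  for (thr in c(0.5, 0.7, 0.9, 0.99)) {
    lo <- check_presence(gene, decoy_genome, identity_threshold = thr)
    hi <- check_presence(gene, decoy_genome, identity_threshold = min(1, thr + 0.2))
    expect_false(!lo && hi)
  }

  # generator truth matrix reproduced exactly by the aligner
  panel <- tiny_panel(n = 6, seed = 406)
  pg <- simulate_pangenome(panel, n_genes = 8, n_planted = 2, carrier_size = 2,
                           gene_length = 300, backbone_length = 4000, seed = 407)
  got <- build_presence_matrix(pg$genes, pg$genomes)
  expect_equal(unclass(got)[rownames(pg$presence_matrix), colnames(pg$presence_matrix)],
               pg$presence_matrix, ignore_attr = TRUE)

  # decoys at 60% identity stay absent: probe presence first (same seed),
  # then regenerate with a decoy aimed at a genuine non-carrier
  probe <- simulate_pangenome(panel, n_genes = 4, n_planted = 0, gene_length = 300,
                              backbone_length = 4000, sequences = FALSE, seed = 408)
  absent <- which(!probe$presence_matrix, arr.ind = TRUE)[1, ]
  dec <- tibble::tibble(gene_id = colnames(probe$presence_matrix)[absent[["col"]]],
                        strain_id = rownames(probe$presence_matrix)[absent[["row"]]],
                        identity = 0.6)
  pg2 <- simulate_pangenome(panel, n_genes = 4, n_planted = 0, gene_length = 300,
                            backbone_length = 4000, decoys = dec, seed = 408)
  expect_false(pg2$presence_matrix[dec$strain_id, dec$gene_id])
  expect_false(check_presence(pg2$genes[[dec$gene_id]], pg2$genomes[[dec$strain_id]]))
})

test_that("bidirectional best hits equal the exhaustive oracle and are symmetric", {
  set.seed(409)
  a <- setNames(random_dna(4, 200), paste0("a", 1:4))
  b <- c(setNames(vapply(a[1:3], mutate_sequence, character(1), rate = 0.05),
                  paste0("b", 1:3)),
         b4 = random_dna(1, 200))
  # identical sets pair perfectly
  self <- bidirectional_best_hits(a, setNames(a, names(a)))
  expect_equal(nrow(self$pairs), 4)

  res <- bidirectional_best_hits(a, b)
  # oracle from an independently computed score matrix
  sm <- matrix(-Inf, length(a), length(b), dimnames = list(names(a), names(b)))
  for (i in names(a)) for (j in names(b)) {
    h <- local_align(a[[i]], b[[j]])
    if (!is.na(h$score)) sm[i, j] <- h$score
  }
  om <- oracle_bbh(sm)
  expect_setequal(paste(res$pairs$a, res$pairs$b),
                  paste(om[, "a"], om[, "b"]))
  # orphan gene stays unpaired
  expect_true("a4" %in% res$unpaired_a || !"a4" %in% res$pairs$a)
  # symmetry: swapping the sets transposes the pairs
  res_t <- bidirectional_best_hits(b, a)
  expect_setequal(paste(res$pairs$a, res$pairs$b),
                  paste(res_t$pairs$b, res_t$pairs$a))
})

test_that("associate_factor reports per-scope statistics with letters", {
  set.seed(410)
  md <- tibble::tibble(strain_id = sprintf("s%02d", 1:12),
                       nod_type = rep(c("A", "B"), each = 6),
                       nod_group = rep(c("A1", "A2", "B1", "B2"), each = 3))
  obs <- tidyr::expand_grid(host_genotype = c("h1", "h2"),
                            strain_id = md$strain_id) |>
    dplyr::mutate(epc_mean = ifelse(strain_id %in% md$strain_id[1:6] &
                                      host_genotype == "h1",
                                    runif(dplyr::n(), 20, 30),
                                    runif(dplyr::n(), 0, 2)))
  res <- associate_factor(obs, md, "nod_type")
  expect_equal(nrow(res), 2)
  expect_lt(res$p_value[res$scope == "h1"], 0.05)
  res_g <- associate_factor(obs, md, "nod_group")
  expect_false(is.null(res_g$letters[[1]]))
})
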