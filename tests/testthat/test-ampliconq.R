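make_pair <- function(r1, r2, q1 = 30, q2 = 30) {
  tibble::tibble(read_id = "p1",
                 r1_seq = r1, r1_qual = phred_string(q1, nchar(r1)),
                 r2_seq = r2, r2_qual = phred_string(q2, nchar(r2)))
}

test_that("merging reconstructs amplicons, handles stagger and rejections", {
  set.seed(201)
  amp <- random_dna(1, 100)
  r1 <- substr(amp, 1, 65)
  r2 <- reverse_complement(substr(amp, 36, 100)) # 30 bp overlap
  m <- merge_pairs(make_pair(r1, r2), min_overlap = 16)
  expect_equal(m$status, "merged")
  expect_equal(m$sequence, amp)
  expect_equal(nchar(m$sequence), 65 + 65 - 30)

  # reverse pair strictly inside the forward read: staggered
  inner <- substr(amp, 21, 60)
  st <- merge_pairs(make_pair(substr(amp, 1, 80), reverse_complement(inner)),
                    allow_stagger = TRUE)
  expect_equal(st$status, "merged")
  expect_equal(st$sequence, inner)
  st2 <- merge_pairs(make_pair(substr(amp, 1, 80), reverse_complement(inner)),
                     allow_stagger = FALSE)
  expect_equal(st2$status, "stagger_rejected")
  expect_true(is.na(st2$sequence))

  # no qualifying overlap
  bad <- merge_pairs(make_pair(random_dna(1, 50), random_dna(1, 50)))
  expect_equal(bad$status, "no_overlap")

  # malformed record
  p <- make_pair(r1, r2); p$r1_qual <- substr(p$r1_qual, 1, 10)
  expect_error(merge_pairs(p), "malformed")
})

test_that("merged qualities follow the min-sum / difference rules", {
  a <- "ACGTACGTACGTACGTACGT"
  pair <- tibble::tibble(read_id = "x",
                         r1_seq = a, r1_qual = phred_string(20, 20),
                         r2_seq = reverse_complement(a), r2_qual = phred_string(30, 20))
  m <- merge_pairs(pair, min_overlap = 16)
  expect_equal(m$status, "merged")
  expect_equal(m$sequence, a)
  # full 20-bp agreement: Q = min(20+30, 41) = 41 everywhere
  expect_equal(unique(utf8ToInt(m$quality) - 33), 41)

  # one conflicting base keeps the higher-quality call with Q = |Q1-Q2|
  b <- a; substr(b, 10, 10) <- "A" # differs from R1's base at that position
  pair2 <- tibble::tibble(read_id = "y",
                          r1_seq = a, r1_qual = phred_string(20, 20),
                          r2_seq = reverse_complement(b), r2_qual = phred_string(30, 20))
  m2 <- merge_pairs(pair2, min_overlap = 16, max_mismatch_fraction = 0.25)
  expect_equal(m2$sequence, b) # higher Q on the R2 side wins
  expect_equal(utf8ToInt(substr(m2$quality, 10, 10)) - 33, 10)

  # EE of merged read never exceeds EE(R1) + EE(R2)
  ee_m <- estimate_expected_error(m2$quality)
  ee_r <- estimate_expected_error(pair2$r1_qual) +
    estimate_expected_error(pair2$r2_qual)
  expect_lte(ee_m, ee_r)
})

test_that("demultiplexing requires exact full-length tags", {
  tags <- c(sampleA = "AAAAAA", sampleB = "CCCCCC")
  reads <- tibble::tibble(sequence = c("AAAAAATTTT", "AAAAATTTTT", "CCCCCCGGGG",
                                       "GAAAAATTTT"),
                          quality = rep(phred_string(30, 10), 4))
  d <- demultiplex(reads, tags)
  expect_equal(d$sample_id, c("sampleA", NA, "sampleB", NA))
  expect_equal(d$sequence[1], "TTTT")
  expect_equal(nchar(d$quality[1]), 4)
  expect_equal(d$sequence[2], "AAAAATTTTT") # untouched when unassigned

  expect_error(demultiplex(reads, c(a = "AAAAAA", b = "AAAAAA")), "duplicate")
})

test_that("primer trimming honors the 2/3 truncation rule at boundaries", {
  set.seed(202)
  fwd <- "ACGGTCTAGCATGACCGTTA" # 20 bp
  rev <- "TGACCAGTTCGGATCACTGA"
  insert <- random_dna(1, 100)
  full <- paste0(fwd, insert, reverse_complement(rev))
  tr <- trim_primers(tibble::tibble(sequence = full), fwd, rev)
  expect_equal(tr$trim_status, "retained")
  expect_equal(tr$sequence, insert)

  # forward primer missing: rejected
  tr2 <- trim_primers(tibble::tibble(sequence = paste0(insert, reverse_complement(rev))),
                      fwd, rev)
  expect_equal(tr2$trim_status, "no_fwd_primer")

  # 3' primer truncated: ceil(2/3 * 20) = 14 bases retained at the end
  trunc14 <- paste0(fwd, insert, substr(reverse_complement(rev), 1, 14))
  tr3 <- trim_primers(tibble::tibble(sequence = trunc14), fwd, rev)
  expect_equal(tr3$trim_status, "retained")
  expect_equal(tr3$sequence, insert)
  # 13 bases is below the floor
  trunc13 <- paste0(fwd, insert, substr(reverse_complement(rev), 1, 13))
  tr4 <- trim_primers(tibble::tibble(sequence = trunc13), fwd, rev)
  expect_equal(tr4$trim_status, "no_rev_primer")

  # one mismatch in a 20-bp primer is within the 0.1 error rate; three are not
  mm <- full
  substr(mm, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(mm, 3, 3))[1]
  expect_equal(trim_primers(tibble::tibble(sequence = mm), fwd, rev)$trim_status,
               "retained")
  mm3 <- full
  for (i in c(3, 7, 11)) {
    substr(mm3, i, i) <- setdiff(c("A", "C", "G", "T"), substr(mm3, i, i))[1]
  }
  expect_equal(trim_primers(tibble::tibble(sequence = mm3), fwd, rev)$trim_status,
               "no_fwd_primer")
})

test_that("expected error matches its closed form", {
  expect_equal(estimate_expected_error(phred_string(20, 10)), 0.1)
  expect_equal(estimate_expected_error(""), 0)
  q <- intToUtf8(c(10, 20, 30) + 33)
  expect_equal(estimate_expected_error(q), 0.1 + 0.01 + 0.001)
  expect_true(is.na(estimate_expected_error(NA_character_)))
})

test_that("dereplication equals a brute-force multiset tally", {
  set.seed(203)
  pool <- sample(random_dna(20, 25), 300, replace = TRUE)
  ee <- runif(300, 0, 2)
  d <- dereplicate(tibble::tibble(sequence = pool, expected_error = ee))
  oracle <- oracle_dereplicate(pool)
  expect_equal(sum(d$abundance), 300)
  expect_equal(nrow(d), nrow(oracle))
  merged <- merge(as.data.frame(d[, c("sequence", "abundance")]), oracle,
                  by = "sequence")
  expect_equal(merged$abundance.x, merged$abundance.y)
  # min EE tracked per unique sequence
  for (i in sample(nrow(d), 5)) {
    expect_equal(d$min_expected_error[i], min(ee[pool == d$sequence[i]]))
  }
  # triple of one string
  d3 <- dereplicate(tibble::tibble(sequence = rep("ACGT", 3),
                                   expected_error = c(0.5, 0.1, 0.2)))
  expect_equal(d3$abundance, 3L)
  expect_equal(d3$min_expected_error, 0.1)
})

test_that("chimera flagging detects constructed hybrids and never alters counts", {
  set.seed(204)
  a <- random_dna(1, 60); b <- random_dna(1, 60)
  hybrid <- paste0(substr(a, 1, 30), substr(b, 31, 60))
  uniques <- tibble::tibble(
    sequence = c(a, b, hybrid, random_dna(1, 60)),
    abundance = c(100L, 90L, 10L, 8L),
    min_expected_error = 0.1)
  fl <- flag_chimeras(uniques)
  expect_true(fl$chimera_flag[fl$sequence == hybrid])
  expect_false(any(fl$chimera_flag[fl$sequence %in% c(a, b)]))
  # counting is independent of flags
  ref <- structure(list(alleles = c(A01 = a, A02 = b, A03 = hybrid),
                        membership = tibble::tibble(allele_id = c("A01", "A02", "A03"),
                                                    strain_id = c("s1", "s2", "s3")),
                        collision_groups = list()),
                   class = "barcode_reference")
  expect_identical(assign_exact(uniques, ref)$count,
                   assign_exact(fl, ref)$count)
})

test_that("exact assignment keeps only strict identity and is order-independent", {
  panel <- tiny_panel(n = 5, allele_length = 50, seed = 205)
  ref <- as_barcode_reference(panel)
  al <- panel$strains$allele
  off <- al[1]; substr(off, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                               substr(off, 10, 10))[1]
  uniq <- tibble::tibble(sample_id = "s",
                         sequence = c(al[1], off, al[3]),
                         abundance = c(7L, 5L, 2L),
                         min_expected_error = 0.1)
  asg <- assign_exact(uniq, ref)
  expect_equal(sum(asg$count), 9)
  expect_equal(attr(asg, "discarded")$discarded, 5)
  asg2 <- assign_exact(uniq[c(3, 1, 2), ], ref)
  expect_equal(dplyr::arrange(tibble::as_tibble(asg), allele_id),
               dplyr::arrange(tibble::as_tibble(asg2), allele_id))
})

test_that("tabulation zero-fills, validates the sheet, and counts collisions at group level", {
  panel <- simulate_panel(n_strains = 4, allele_length = 30,
                          collision_spec = list(g = c("S01", "S02")), seed = 206)
  ref <- as_barcode_reference(panel)
  uniq <- tibble::tibble(sample_id = "a",
                         sequence = unname(ref$alleles),
                         abundance = c(10L, 3L, 1L),
                         min_expected_error = 0.1)
  asg <- assign_exact(uniq, ref)
  sheet <- tibble::tibble(sample_id = c("a", "b"))
  ct <- tabulate_counts(asg, sheet, ref)
  expect_equal(nrow(ct), 6) # 3 allele groups x 2 samples
  expect_true("S01+S02" %in% ct$strain_id)
  expect_equal(sum(ct$count[ct$sample_id == "b"]), 0)
  expect_equal(sum(ct$count), 14)
  expect_error(tabulate_counts(asg, tibble::tibble(sample_id = "zzz"), ref),
               "absent from sheet")
})

test_that("the processing funnel is monotone and the round trip matches truth at zero error", {
  panel <- tiny_panel(n = 6, allele_length = 80, seed = 207)
  mx <- simulate_host_propensities(panel, hosts = c("H1", "H2"), n_replicates = 2,
                                   depth = 400, seed = 208)
  rd <- simulate_reads(panel, mx, read_length = 90, error_rate = 0, seed = 209)
  sheet <- dplyr::inner_join(
    dplyr::distinct(mx, sample_id, host_genotype, replicate),
    rd$tags, by = "sample_id")
  q <- quantify_reads(rd$reads, sheet, as_barcode_reference(panel))
  log <- q$log
  expect_true(log$raw >= log$merged)
  expect_true(log$merged >= log$demultiplexed)
  expect_true(log$demultiplexed >= log$primer_retained)
  expect_true(log$primer_retained >= log$assigned)
  expect_equal(log$assigned, 1600) # zero error: everything identical

  truth <- rd$truth_counts |> dplyr::rename(count_truth = reads)
  cmp <- dplyr::left_join(q$counts, truth,
                          by = c("sample_id", "strain_id")) |>
    dplyr::mutate(count_truth = tidyr::replace_na(count_truth, 0L))
  expect_equal(cmp$count, cmp$count_truth)

  # at error rate e the assigned fraction is near (1-e)^L-driven expectations
  e <- 0.02
  rde <- simulate_reads(panel, mx, read_length = 90, error_rate = e, seed = 210)
  sheet_e <- dplyr::inner_join(
    dplyr::distinct(mx, sample_id, host_genotype, replicate),
    rde$tags, by = "sample_id")
  qe <- quantify_reads(rde$reads, sheet_e, as_barcode_reference(panel))
  expect_lt(qe$log$assigned, qe$log$primer_retained)
  expect_gt(qe$log$assigned, 0)
})
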