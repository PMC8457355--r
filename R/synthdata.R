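# Synthetic study generator: strain panels with barcode alleles, pangenomes
# with planted host-effect genes, host-specific inoculum mixtures, and
# error-bearing paired reads with full ground truth.

#' Default amplification primers used by the simulator
#'
#' 20-bp primer pair flanking the barcode allele in every simulated marker
#' sequence. Any primer pair can be supplied instead.
#' @export
default_primers <- function() {
  c(fwd = "ACGGTCTAGCATGACCGTTA", rev = "TGACCAGTTCGGATCACTGA")
}

#' Simulate a strain panel with barcode alleles
#'
#' Builds a panel of strains whose marker sequences each contain exactly one
#' forward primer site, a fixed-length variable allele window, and one
#' reverse primer site (reverse-complemented), embedded in conserved flanks.
#' Collision groups let two or more strains share an allele, as happens when
#' closely related strains are indistinguishable at the barcode locus.
#'
#' @param n_strains Number of strains in the panel.
#' @param allele_length Allele (inter-primer window) length in bp.
#' @param n_distinct_alleles Number of distinct alleles to realize; when
#'   smaller than `n_strains` and no `collision_spec` is given, surplus
#'   strains are merged pairwise into the first alleles.
#' @param collision_spec Optional named list of character vectors; each
#'   element lists the strain ids sharing one allele. Strains not listed get
#'   their own allele.
#' @param primer_fwd,primer_rev Primer sequences (plus-strand orientation).
#' @param flank_length Conserved flank length on each side of the primer
#'   sites, so the marker alignment has context beyond the amplicon.
#' @param seed Integer seed; fixed seeds give byte-identical panels.
#' @return An object of class `strain_panel`: a list with a `strains` tibble
#'   (`strain_id`, `allele_id`, `allele`, `marker_sequence`), the allele
#'   table, primers and parameters.
#' @export
simulate_panel <- function(n_strains = 32, allele_length = 309,
                           n_distinct_alleles = NULL, collision_spec = NULL,
                           primer_fwd = default_primers()[["fwd"]],
                           primer_rev = default_primers()[["rev"]],
                           flank_length = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_strains < 1) abort("n_strains must be positive")
  if (nchar(primer_fwd) == 0 || nchar(primer_rev) == 0) abort("primers must be non-empty")
  strain_ids <- sprintf("S%02d", seq_len(n_strains))

  if (!is.null(collision_spec)) {
    all_members <- unlist(collision_spec, use.names = FALSE)
    if (anyDuplicated(all_members))
      abort("infeasible collision_spec: a strain appears in more than one group")
    unknown <- setdiff(all_members, strain_ids)
    if (length(unknown))
      abort(sprintf("infeasible collision_spec: unknown strain(s) %s",
                    paste(unknown, collapse = ", ")))
    if (any(lengths(collision_spec) < 2))
      abort("infeasible collision_spec: every collision group needs >= 2 strains")
    singletons <- setdiff(strain_ids, all_members)
    implied <- length(collision_spec) + length(singletons)
    if (!is.null(n_distinct_alleles) && n_distinct_alleles != implied)
      abort(sprintf(paste0("infeasible collision_spec: group sizes imply %d distinct ",
                           "alleles over %d strains, but n_distinct_alleles = %d"),
                    implied, n_strains, n_distinct_alleles))
    n_distinct_alleles <- implied
    groups <- c(collision_spec, as.list(singletons))
  } else {
    n_distinct_alleles <- n_distinct_alleles %||% n_strains
    if (n_distinct_alleles < 1 || n_distinct_alleles > n_strains)
      abort("n_distinct_alleles must be in [1, n_strains]")
    n_extra <- n_strains - n_distinct_alleles
    groups <- as.list(strain_ids[seq_len(n_distinct_alleles)])
    for (k in seq_len(n_extra)) {
      target <- ((k - 1L) %% n_distinct_alleles) + 1L
      groups[[target]] <- c(groups[[target]], strain_ids[n_distinct_alleles + k])
    }
  }
  names(groups) <- sprintf("A%02d", seq_along(groups))

  rc_rev <- reverse_complement(primer_rev)
  flank5 <- random_dna(1, flank_length)
  flank3 <- random_dna(1, flank_length)
  ok_marker <- function(marker) {
    length(gregexpr(primer_fwd, marker, fixed = TRUE)[[1]]) == 1 &&
      gregexpr(primer_fwd, marker, fixed = TRUE)[[1]][1] > 0 &&
      length(gregexpr(rc_rev, marker, fixed = TRUE)[[1]]) == 1 &&
      gregexpr(rc_rev, marker, fixed = TRUE)[[1]][1] > 0
  }
  alleles <- character(n_distinct_alleles)
  seen <- character(0)
  for (i in seq_len(n_distinct_alleles)) {
    repeat {
      cand <- random_dna(1, allele_length)
      marker <- paste0(flank5, primer_fwd, cand, rc_rev, flank3)
      if (!(cand %in% seen) && ok_marker(marker)) break
    }
    alleles[i] <- cand
    seen <- c(seen, cand)
  }
  names(alleles) <- names(groups)

  strains <- purrr::map2_dfr(names(groups), groups, function(aid, members) {
    tibble(strain_id = members, allele_id = aid, allele = alleles[[aid]])
  }) |>
    mutate(marker_sequence = paste0(flank5, primer_fwd, .data$allele, rc_rev, flank3)) |>
    arrange(.data$strain_id)

  structure(list(
    strains = strains, alleles = alleles,
    primer_fwd = primer_fwd, primer_rev = primer_rev,
    allele_length = allele_length, flank_length = flank_length,
    collision_groups = groups[lengths(groups) >= 2], seed = seed
  ), class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf("<strain_panel> %d strains, %d distinct alleles (%d bp), %d collision group(s)\n",
              nrow(x$strains), length(x$alleles), x$allele_length,
              length(x$collision_groups)))
  invisible(x)
}

#' Simulate a pangenome with planted accessory genes
#'
#' Generates per-strain genomes (a genospecies-structured backbone plus the
#' accessory genes each strain carries and a repABC replicon cassette),
#' together with the ground-truth presence/absence matrix. `n_planted` genes
#' are reserved as host-effect genes carried by `carrier_size` strains each;
#' the remaining null genes follow a cloud-plus-core frequency spectrum by
#' default (very rare or near-universal), with a beta-distributed shell
#' available via `spectrum = "shell"`.
#'
#' @param panel A `strain_panel`.
#' @param n_genes Total number of accessory genes.
#' @param n_planted Number of planted (host-effect) genes; must be
#'   `<= n_genes`.
#' @param gene_length Gene length in bp; must be at least `seed_k`, the
#'   aligner seed length, otherwise presence is undetectable by construction.
#' @param carrier_size Number of strains carrying each planted gene.
#' @param spectrum Null-gene frequency spectrum: `"cloud_core"` (default) or
#'   `"shell"`.
#' @param n_genospecies Number of genome clusters to plant in the backbone.
#' @param within_gs_divergence,between_gs_divergence Per-base substitution
#'   rates of strain backbones within, and genospecies backbones between,
#'   clusters.
#' @param backbone_length Shared backbone length in bp.
#' @param n_replicon_groups Number of repABC replicon (Rh) classes.
#' @param decoys Optional tibble (`gene_id`, `strain_id`, `identity`) of
#'   diverged gene copies to insert into non-carriers; truth records them
#'   absent.
#' @param seed_k Seed length the downstream aligner will use (feasibility
#'   check only).
#' @param sequences Generate gene/genome/replicon sequences? Set FALSE for
#'   presence-truth-only studies (association statistics), which is much
#'   faster.
#' @param seed Integer seed.
#' @return An object of class `synthetic_pangenome` with the truth presence
#'   tibble and matrix, gene and genome sequences, planted gene ids,
#'   genospecies truth, replicon cassettes and repABC references.
#' @export
simulate_pangenome <- function(panel, n_genes = 40, n_planted = 3,
                               gene_length = 900, carrier_size = 5,
                               spectrum = c("cloud_core", "shell"),
                               n_genospecies = 3,
                               within_gs_divergence = 0.005,
                               between_gs_divergence = 0.06,
                               backbone_length = 20000,
                               n_replicon_groups = 2,
                               decoys = NULL, seed_k = 11, sequences = TRUE,
                               seed = NULL) {
  stopifnot(inherits(panel, "strain_panel"))
  spectrum <- match.arg(spectrum)
  if (!is.null(seed)) set.seed(seed)
  if (n_planted > n_genes) abort("n_planted must be <= n_genes")
  if (gene_length < seed_k)
    abort(sprintf("gene_length (%d) is below the aligner seed length (%d): presence would be undetectable",
                  gene_length, seed_k))
  strains <- panel$strains$strain_id
  n <- length(strains)
  if (n_planted > 0 && carrier_size > n)
    abort("carrier_size exceeds the number of strains")

  gene_ids <- c(if (n_planted > 0) sprintf("pg%02d", seq_len(n_planted)),
                if (n_genes > n_planted) sprintf("g%03d", seq_len(n_genes - n_planted)))

  presence <- matrix(FALSE, n, n_genes, dimnames = list(strains, gene_ids))
  planted <- character(0)
  if (n_planted > 0) {
    planted <- gene_ids[seq_len(n_planted)]
    seen_sets <- character(0)
    for (g in planted) {
      repeat {
        carriers <- sort(sample(strains, carrier_size))
        key <- paste(carriers, collapse = ",")
        if (!key %in% seen_sets) break
      }
      seen_sets <- c(seen_sets, key)
      presence[carriers, g] <- TRUE
    }
  }
  null_genes <- setdiff(gene_ids, planted)
  for (g in null_genes) {
    m <- if (spectrum == "cloud_core") {
      if (runif(1) < 0.5) sample(seq_len(min(4L, n - 1L)), 1)
      else sample(seq(max(n - 3L, 1L), n), 1)
    } else {
      max(1L, min(n - 1L, round(n * rbeta_one(0.5, 0.5))))
    }
    presence[sample(strains, m), g] <- TRUE
  }

  gs_idx <- rep(seq_len(n_genospecies), each = ceiling(n / n_genospecies))[seq_len(n)]
  gs_of <- setNames(sprintf("gs%d", gs_idx), strains)

  if (!is.null(decoys)) {
    check_columns(decoys, c("gene_id", "strain_id", "identity"), "decoys")
    if (any(presence[cbind(decoys$strain_id, decoys$gene_id)]))
      abort("decoys may only target non-carrier strains")
  }

  genes <- genomes <- replicons <- repA_refs <- repB <- repC <- NULL
  if (sequences) {
    genes <- setNames(random_dna(n_genes, gene_length), gene_ids)
    root <- random_dna(1, backbone_length)
    gs_backbones <- setNames(
      vapply(seq_len(n_genospecies), function(i) mutate_sequence(root, between_gs_divergence),
             character(1)),
      sprintf("gs%d", seq_len(n_genospecies)))

    rep_len <- 600
    repA_base <- random_dna(1, rep_len)
    repA_refs <- setNames(
      c(repA_base,
        vapply(seq_len(max(0, n_replicon_groups - 1)),
               function(i) mutate_sequence(repA_base, 0.15), character(1))),
      sprintf("Rh%d", seq_len(n_replicon_groups)))
    repB <- random_dna(1, rep_len)
    repC <- random_dna(1, rep_len)
    rh_of <- setNames(sprintf("Rh%d", rep(seq_len(n_replicon_groups), length.out = n)), strains)

    replicons <- tibble(
      strain_id = strains,
      rh_group = unname(rh_of[strains]),
      sequence = vapply(strains, function(s) {
        paste0(random_dna(1, 300), repA_refs[[rh_of[[s]]]], random_dna(1, 100),
               repB, random_dna(1, 100), repC, random_dna(1, 300))
      }, character(1)))

    genomes <- setNames(vapply(strains, function(s) {
      backbone <- mutate_sequence(gs_backbones[[gs_of[[s]]]], within_gs_divergence)
      carried <- gene_ids[presence[s, ]]
      extra <- character(0)
      if (!is.null(decoys)) {
        d <- decoys[decoys$strain_id == s, , drop = FALSE]
        if (nrow(d)) {
          extra <- vapply(seq_len(nrow(d)), function(i) {
            mutate_sequence(genes[[d$gene_id[i]]], 1 - d$identity[i])
          }, character(1))
        }
      }
      paste0(c(backbone, unname(genes[carried]), extra,
               replicons$sequence[replicons$strain_id == s]), collapse = "")
    }, character(1)), strains)
  }

  presence_tbl <- as_tibble(as.data.frame.table(presence, stringsAsFactors = FALSE)) |>
    setNames(c("strain_id", "gene_id", "present")) |>
    as_tibble()

  structure(list(
    presence = presence_tbl, presence_matrix = presence,
    genes = genes, genomes = genomes, planted_genes = planted,
    genospecies = tibble(strain_id = strains, genospecies = unname(gs_of[strains])),
    replicons = replicons, repA_references = repA_refs,
    repB_reference = repB, repC_reference = repC,
    params = list(n_genes = n_genes, n_planted = n_planted,
                  gene_length = gene_length, carrier_size = carrier_size,
                  spectrum = spectrum, seed = seed)
  ), class = "synthetic_pangenome")
}

# one draw from Beta(a, b) without loading extra namespaces
rbeta_one <- function(a, b) {
  x <- rgamma(1, a); y <- rgamma(1, b); x / (x + y)
}

#' Assign planted genes to host genotypes as multiplicative effects
#'
#' @param pangenome A `synthetic_pangenome`.
#' @param hosts Character vector of host genotype labels; planted genes are
#'   assigned to hosts cyclically.
#' @param effect_size Multiplicative propensity factor for carriers
#'   (1 = null).
#' @return Tibble (`gene_id`, `host_genotype`, `effect_size`).
#' @export
planted_effects <- function(pangenome, hosts, effect_size = 10) {
  stopifnot(inherits(pangenome, "synthetic_pangenome"))
  pg <- pangenome$planted_genes
  if (!length(pg)) return(tibble(gene_id = character(), host_genotype = character(),
                                 effect_size = numeric()))
  tibble(gene_id = pg,
         host_genotype = rep(hosts, length.out = length(pg)),
         effect_size = effect_size)
}

#' Simulate host-specific inoculum mixtures
#'
#' Per host, a base propensity vector (uniform times the product of the
#' effect sizes of carried planted genes) is normalized to the host truth;
#' each biological replicate draws its proportions from a Dirichlet
#' distribution centered on that truth.
#'
#' @param panel A `strain_panel`.
#' @param presence Ground-truth presence: a `synthetic_pangenome`, a logical
#'   strains-by-genes matrix, or NULL when `effects` is empty.
#' @param effects Tibble (`gene_id`, `host_genotype`, `effect_size`);
#'   zero rows mean equal propensities everywhere.
#' @param hosts Character vector of host genotype labels.
#' @param n_replicates Biological replicates per host.
#' @param dirichlet_concentration Total Dirichlet concentration; `Inf`
#'   removes replicate noise.
#' @param depth Read pairs per sample.
#' @param seed Integer seed.
#' @return Object of class `truth_mixtures`: a tibble (`sample_id`,
#'   `host_genotype`, `replicate`, `strain_id`, `proportion`, `depth`) with a
#'   `host_truth` attribute holding the noise-free per-host proportions.
#' @export
simulate_host_propensities <- function(panel, presence = NULL, effects = NULL,
                                       hosts, n_replicates = 4,
                                       dirichlet_concentration = 100,
                                       depth = 14203, seed = NULL) {
  stopifnot(inherits(panel, "strain_panel"))
  if (!is.null(seed)) set.seed(seed)
  if (depth <= 0) abort("depth must be positive")
  strains <- panel$strains$strain_id
  n <- length(strains)
  pm <- NULL
  if (inherits(presence, "synthetic_pangenome")) pm <- presence$presence_matrix
  else if (is.matrix(presence)) pm <- presence
  effects <- effects %||% tibble(gene_id = character(), host_genotype = character(),
                                 effect_size = numeric())
  if (nrow(effects)) {
    check_columns(effects, c("gene_id", "host_genotype", "effect_size"), "effects")
    if (is.null(pm)) abort("effects supplied without a presence matrix")
    bad_host <- setdiff(effects$host_genotype, hosts)
    if (length(bad_host)) abort(sprintf("effects reference unknown host(s): %s",
                                        paste(bad_host, collapse = ", ")))
    bad_gene <- setdiff(effects$gene_id, colnames(pm))
    if (length(bad_gene)) abort(sprintf("effects reference unknown gene(s): %s",
                                        paste(bad_gene, collapse = ", ")))
  }

  host_truth <- vapply(hosts, function(h) {
    base <- rep(1, n)
    eff <- effects[effects$host_genotype == h, , drop = FALSE]
    if (nrow(eff)) {
      for (i in seq_len(nrow(eff))) {
        carriers <- pm[strains, eff$gene_id[i]]
        base[carriers] <- base[carriers] * eff$effect_size[i]
      }
    }
    tot <- sum(base)
    if (tot <= 0) abort(sprintf("zero total propensity for host %s", h))
    base / tot
  }, numeric(n))
  rownames(host_truth) <- strains

  out <- purrr::map_dfr(hosts, function(h) {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      p <- if (is.infinite(dirichlet_concentration)) host_truth[, h] else {
        g <- rgamma(n, shape = dirichlet_concentration * host_truth[, h])
        if (sum(g) <= 0) host_truth[, h] else g / sum(g)
      }
      tibble(sample_id = sprintf("%s_R%d", h, r), host_genotype = h,
             replicate = r, strain_id = strains, proportion = unname(p),
             depth = as.integer(depth))
    })
  })
  structure(out, class = c("truth_mixtures", class(out)),
            host_truth = host_truth,
            params = list(n_replicates = n_replicates,
                          dirichlet_concentration = dirichlet_concentration,
                          depth = depth))
}

#' Simulate per-strain read counts directly from mixtures
#'
#' Multinomial sampling of each sample's `depth` reads over its mixture
#' proportions, bypassing read-level simulation. Useful when only the count
#' table matters (e.g. association statistics at scale).
#'
#' @param mixtures A `truth_mixtures` tibble.
#' @param seed Integer seed.
#' @return Long count tibble (`sample_id`, `strain_id`, `count`).
#' @export
simulate_counts <- function(mixtures, seed = NULL) {
  check_columns(mixtures, c("sample_id", "strain_id", "proportion", "depth"), "mixtures")
  if (!is.null(seed)) set.seed(seed)
  mixtures |>
    group_by(.data$sample_id) |>
    mutate(count = as.integer(rmultinom(1, .data$depth[[1]], .data$proportion))) |>
    ungroup() |>
    select("sample_id", "strain_id", "count")
}

#' Simulate tagged paired-end amplicon reads
#'
#' Each sample's read pairs are drawn multinomially from its mixture
#' proportions. The sequenced molecule is `tag + primer_fwd + allele +
#' revcomp(primer_rev)`; the forward read covers its 5' end and the reverse
#' read the reverse complement of its 3' end, overlapping so that merging
#' reconstructs the full molecule. Substitution errors are i.i.d. per base at
#' `error_rate`, realized through a two-state quality model: each base is
#' low-quality (phred `q_low`) with the mixing probability that makes the
#' marginal per-base error rate equal `error_rate`, and high-quality
#' (`q_high`) otherwise, so quality strings are consistent with the error
#' process.
#'
#' @param panel A `strain_panel`.
#' @param mixtures A `truth_mixtures` tibble.
#' @param read_length Read length in bp.
#' @param error_rate Marginal per-base substitution probability, in
#'   \[0, 0.25).
#' @param tags Optional named character vector of sample tags (5' of the
#'   forward read); generated when NULL.
#' @param tag_length Tag length when generating tags.
#' @param q_high,q_low Phred scores of the two quality states.
#' @param min_overlap Overlap the downstream merger requires; molecules
#'   longer than `2*read_length - min_overlap` are rejected as unmergeable.
#' @param seed Integer seed; fixed seeds give byte-identical output.
#' @return Object of class `synthetic_reads`: list with `reads` (tibble
#'   `read_id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`, plus truth columns
#'   `true_sample` and `true_strain`), `tags`, `truth_counts`, and `params`.
#' @export
simulate_reads <- function(panel, mixtures, read_length = 250,
                           error_rate = 0.005, tags = NULL, tag_length = 6,
                           q_high = 38, q_low = 12, min_overlap = 16,
                           seed = NULL) {
  stopifnot(inherits(panel, "strain_panel"))
  if (!is.null(seed)) set.seed(seed)
  if (error_rate < 0 || error_rate >= 0.25) abort("error_rate must be in [0, 0.25)")
  if (read_length < nchar(panel$primer_fwd) + 1)
    abort("read_length must exceed the primer length")
  samples <- mixtures |> distinct(.data$sample_id, .data$host_genotype,
                                  .data$replicate, .data$depth)
  if (is.null(tags)) {
    repeat {
      tags <- setNames(random_dna(nrow(samples), tag_length), samples$sample_id)
      if (!anyDuplicated(tags)) break
    }
  } else {
    if (anyDuplicated(tags)) abort("tags must be pairwise distinct")
    missing <- setdiff(samples$sample_id, names(tags))
    if (length(missing)) abort(sprintf("no tag for sample(s): %s",
                                       paste(missing, collapse = ", ")))
  }

  rc_rev <- reverse_complement(panel$primer_rev)
  allele_of <- setNames(panel$strains$allele, panel$strains$strain_id)
  amplicon_len <- nchar(panel$primer_fwd) + panel$allele_length + nchar(panel$primer_rev)
  mol_len <- tag_length + amplicon_len
  if (mol_len > 2 * read_length - min_overlap)
    abort(sprintf("molecule (%d bp) exceeds 2*read_length - min_overlap (%d bp): unmergeable by construction",
                  mol_len, 2 * read_length - min_overlap))

  e_high <- 10^(-q_high / 10)
  e_low <- 10^(-q_low / 10)
  if (error_rate > e_high) {
    p_low <- (error_rate - e_high) / (e_low - e_high)
  } else {
    p_low <- 0
    e_high <- error_rate # below the high-quality floor: uniform rare errors
  }
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("A","C","G","T"), c("1","2","3")))

  per_sample <- purrr::map(seq_len(nrow(samples)), function(si) {
    sid <- samples$sample_id[si]
    mix <- mixtures[mixtures$sample_id == sid, , drop = FALSE]
    counts <- as.integer(rmultinom(1, samples$depth[si], mix$proportion))
    strains <- mix$strain_id
    molecules <- paste0(tags[[sid]], panel$primer_fwd, allele_of[strains], rc_rev)
    r1_tpl <- substr(molecules, 1, read_length)
    r2_tpl <- reverse_complement(substr(molecules, pmax(1, nchar(molecules) - read_length + 1),
                                        nchar(molecules)))
    idx <- rep(seq_along(strains), counts)
    n_reads <- length(idx)
    if (n_reads == 0) {
      return(list(reads = tibble(read_id = character(), r1_seq = character(),
                                 r1_qual = character(), r2_seq = character(),
                                 r2_qual = character(), true_sample = character(),
                                 true_strain = character()),
                  counts = tibble(sample_id = sid, strain_id = strains,
                                  reads = counts)))
    }
    make_mate <- function(tpl) {
      L <- read_length
      seqs <- tpl[idx]
      nbase <- n_reads * L
      low <- if (p_low > 0) runif(nbase) < p_low else rep(FALSE, nbase)
      prob <- ifelse(low, e_low, e_high)
      err <- runif(nbase) < prob
      quals <- .qual_strings_cpp(low, L, q_high, q_low)
      hit <- which(err)
      if (length(hit)) {
        ri <- ((hit - 1L) %/% L) + 1L
        pp <- ((hit - 1L) %% L) + 1L
        orig <- substring(tpl[idx[ri]], pp, pp)
        nb <- alt[cbind(orig, sample.int(3L, length(hit), replace = TRUE))]
        seqs <- .apply_subs_cpp(seqs, ri, pp, nb)
      }
      list(seq = seqs, qual = quals)
    }
    m1 <- make_mate(r1_tpl)
    m2 <- make_mate(r2_tpl)
    ord <- sample.int(n_reads)
    list(reads = tibble(
      read_id = sprintf("%s_%06d", sid, seq_len(n_reads)),
      r1_seq = m1$seq[ord], r1_qual = m1$qual[ord],
      r2_seq = m2$seq[ord], r2_qual = m2$qual[ord],
      true_sample = sid, true_strain = strains[idx][ord]),
      counts = tibble(sample_id = sid, strain_id = strains, reads = counts))
  })

  structure(list(
    reads = purrr::map_dfr(per_sample, "reads"),
    tags = tibble(sample_id = samples$sample_id, tag = unname(tags[samples$sample_id])),
    truth_counts = purrr::map_dfr(per_sample, "counts"),
    params = list(read_length = read_length, error_rate = error_rate,
                  tag_length = tag_length, q_high = q_high, q_low = q_low,
                  seed = seed)
  ), class = "synthetic_reads")
}

#' Simulate a complete mixed-inoculation metabarcoding study
#'
#' Convenience wrapper chaining [simulate_panel()], [simulate_pangenome()],
#' [planted_effects()], [simulate_host_propensities()] and
#' [simulate_reads()] with one master seed, and assembling the sample sheet
#' and barcode reference the processing chain needs. Defaults mirror the
#' study design this package models: 9 host genotypes x 4 replicates, a
#' 32-strain panel with one 2-strain barcode collision, ~1.4e4 read pairs per
#' sample, 2 x 250 bp reads, 0.5% per-base error.
#'
#' @param hosts Host genotype labels.
#' @param n_replicates Biological replicates per host.
#' @param n_strains,n_distinct_alleles,allele_length Panel layout.
#' @param depth Read pairs per sample.
#' @param error_rate Per-base substitution rate.
#' @param n_genes,n_planted,effect_size Pangenome and planted-effect layout;
#'   `n_planted = 0` disables the pangenome stage's effects.
#' @param dirichlet_concentration Replicate noise (larger = tighter).
#' @param read_length Read length in bp.
#' @param seed Master seed; stage seeds are derived from it.
#' @param reads Set FALSE to skip read simulation (mixtures only).
#' @return List with `panel`, `pangenome`, `effects`, `mixtures`, `reads`
#'   (or NULL), `sample_sheet`, and `reference` (a `barcode_reference`).
#' @export
simulate_study <- function(hosts = c("FO", "FD", "FT", "PK", "PI", "PJ", "LF", "LR", "LA"),
                           n_replicates = 4, n_strains = 32,
                           n_distinct_alleles = n_strains - 1,
                           allele_length = 309, depth = 14203,
                           error_rate = 0.005, n_genes = 40, n_planted = 3,
                           effect_size = 10, dirichlet_concentration = 100,
                           read_length = 250, seed = 1, reads = TRUE) {
  panel <- simulate_panel(n_strains = n_strains, allele_length = allele_length,
                          n_distinct_alleles = n_distinct_alleles,
                          seed = derive_seed(seed, 1))
  pangenome <- simulate_pangenome(panel, n_genes = n_genes, n_planted = n_planted,
                                  seed = derive_seed(seed, 2))
  effects <- planted_effects(pangenome, hosts, effect_size = effect_size)
  mixtures <- simulate_host_propensities(panel, pangenome, effects, hosts,
                                         n_replicates = n_replicates,
                                         dirichlet_concentration = dirichlet_concentration,
                                         depth = depth, seed = derive_seed(seed, 3))
  rd <- if (reads) simulate_reads(panel, mixtures, read_length = read_length,
                                  error_rate = error_rate,
                                  seed = derive_seed(seed, 4)) else NULL
  sheet <- mixtures |>
    distinct(.data$sample_id, .data$host_genotype, .data$replicate)
  if (!is.null(rd)) sheet <- left_join(sheet, rd$tags, by = "sample_id")
  list(panel = panel, pangenome = pangenome, effects = effects,
       mixtures = mixtures, reads = rd, sample_sheet = sheet,
       reference = as_barcode_reference(panel))
}
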