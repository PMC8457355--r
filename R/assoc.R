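# Genotype-phenotype association: Kruskal-Wallis (tie-corrected, optional
# exact permutation p), Dunn post hoc with Bonferroni and compact letters,
# species-level pooling, top-vs-bottom gene presence/absence contrast, and
# the seed-and-extend presence engine with bidirectional best hits.

kw_statistic <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, groups, mean)
  nn <- tapply(r, groups, length)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)
  h <- 12 / (N * (N + 1)) * sum(nn * (rbar - (N + 1) / 2)^2)
  h / C
}

# all distinct assignments of N items into labeled groups of the given sizes
enumerate_assignments <- function(sizes) {
  N <- sum(sizes)
  out <- list()
  recurse <- function(remaining, gi, acc) {
    if (gi > length(sizes)) { out[[length(out) + 1]] <<- acc; return(invisible()) }
    if (length(remaining) == sizes[gi]) {
      acc[remaining] <- gi
      recurse(integer(0), gi + 1, acc)
    } else {
      # fix the smallest remaining index into this group iff the group is
      # still open, via combn over the rest
      picks <- combn(remaining, sizes[gi], simplify = FALSE)
      for (p in picks) {
        acc2 <- acc; acc2[p] <- gi
        recurse(setdiff(remaining, p), gi + 1, acc2)
      }
    }
  }
  recurse(seq_len(N), 1, integer(N))
  out
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Computes the tie-corrected H statistic with a chi-square p-value on
#' `groups - 1` degrees of freedom; for small samples an exact permutation
#' p-value (full enumeration of group-label assignments) is available.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @param exact `"never"` (chi-square only), `"always"` (exact permutation
#'   p), or `"auto"` (exact when `length(values) <= max_exact_n`).
#' @param max_exact_n Size cutoff for `exact = "auto"`.
#' @return Object of class `epc_kw` with `statistic`, `df`, `p_value`,
#'   `p_exact` (NA unless computed), `n`, and per-group medians/sizes.
#' @export
kruskal_wallis <- function(values, groups, exact = c("never", "auto", "always"),
                           max_exact_n = 8) {
  exact <- match.arg(exact)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(as.factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2) abort("need at least two groups")
  if (length(values) < 3) abort("need at least three observations")
  H <- kw_statistic(values, groups)
  p <- if (length(unique(values)) == 1) 1 else pchisq(H, df = k - 1, lower.tail = FALSE)
  p_exact <- NA_real_
  if (exact == "always" || (exact == "auto" && length(values) <= max_exact_n)) {
    sizes <- as.integer(table(groups))
    assigns <- enumerate_assignments(sizes)
    hs <- vapply(assigns, function(a) kw_statistic(values, a), numeric(1))
    p_exact <- mean(hs >= H - 1e-12)
  }
  structure(list(statistic = H, df = k - 1L, p_value = p, p_exact = p_exact,
                 n = length(values),
                 groups = tibble(group = levels(groups),
                                 n = as.integer(table(groups)),
                                 median = as.numeric(tapply(values, groups, median)))),
            class = "epc_kw")
}

#' @export
print.epc_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  if (!is.na(x$p_exact)) cat(sprintf("  exact permutation p = %.4g\n", x$p_exact))
  invisible(x)
}

#' @method tidy epc_kw
#' @export
tidy.epc_kw <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         p_exact = x$p_exact, n = x$n)
}

#' @method glance epc_kw
#' @export
glance.epc_kw <- function(x, ...) tidy(x)

#' Dunn post hoc test with Bonferroni correction and compact letters
#'
#' Pairwise z statistics `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) *
#' (1/n_i + 1/n_j))` with tie term `T = sum(t^3 - t) / (12 (N - 1))`,
#' two-sided p-values multiplied by the number of pairs (capped at 1), and a
#' compact letter display built by greedy insert-absorb over groups sorted by
#' decreasing median: two groups share a letter iff not significantly
#' different at `alpha`.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param alpha Significance level for the letter display.
#' @return Object of class `epc_dunn` with `pairs` (tibble `group1`,
#'   `group2`, `z`, `p_value`, `p_adjusted`) and `letters` (tibble `group`,
#'   `median`, `n`, `letters`).
#' @export
dunn_posthoc <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(as.factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2) abort("need at least two groups")
  if (any(table(groups) == 0)) abort("empty group")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  nn <- tapply(r, groups, length)
  ties <- table(values)
  Tt <- sum(ties^3 - ties) / (12 * (N - 1))
  pair_idx <- combn(levels(groups), 2, simplify = FALSE)
  npairs <- length(pair_idx)
  pairs <- purrr::map_dfr(pair_idx, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - Tt) * (1 / nn[[i]] + 1 / nn[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    tibble(group1 = i, group2 = j, z = z, p_value = p,
           p_adjusted = min(1, p * npairs))
  })
  medians <- tapply(values, groups, median)
  ord <- names(sort(medians, decreasing = TRUE))
  nonsig <- function(a, b) {
    if (a == b) return(TRUE)
    row <- pairs[(pairs$group1 == a & pairs$group2 == b) |
                   (pairs$group1 == b & pairs$group2 == a), ]
    row$p_adjusted[[1]] > alpha
  }
  sets <- list()
  for (g in ord) {
    added <- FALSE
    for (s in seq_along(sets)) {
      if (g %in% sets[[s]]) { added <- TRUE; next }
      if (all(vapply(sets[[s]], function(m) nonsig(g, m), logical(1)))) {
        sets[[s]] <- c(sets[[s]], g); added <- TRUE
      }
    }
    if (!added) {
      new_set <- g
      for (m in setdiff(ord, g)) {
        if (m %in% new_set) next
        if (nonsig(g, m) &&
            all(vapply(new_set, function(x) x %in% c(g, m) || nonsig(m, x), logical(1))))
          new_set <- c(new_set, m)
      }
      sets[[length(sets) + 1]] <- new_set
    }
  }
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
        (length(sets[[i]]) < length(sets[[j]]) || i > j)) keep[i] <- FALSE
  }
  sets <- sets[keep]
  letter_of <- vapply(ord, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))], collapse = "")
  }, character(1))
  structure(list(
    pairs = pairs,
    letters = tibble(group = ord, median = as.numeric(medians[ord]),
                     n = as.integer(nn[ord]), letters = unname(letter_of)),
    alpha = alpha
  ), class = "epc_dunn")
}

#' @export
print.epc_dunn <- function(x, ...) {
  cat(sprintf("Dunn post hoc (Bonferroni), alpha = %g\n", x$alpha))
  print(x$letters)
  invisible(x)
}

#' @method tidy epc_dunn
#' @export
tidy.epc_dunn <- function(x, ...) x$pairs

#' Pool cultivar-level EPC observations to the plant-species level
#'
#' Each strain-by-cultivar mean EPC becomes one observation of its species
#' pool, so a species with two cultivars contributes `2 * n_strains`
#' observations (pseudo-replication preserved deliberately, as the per-level
#' n values are reported).
#'
#' @param epc_summary Tibble (`host_genotype`, `strain_id`, `epc_mean`).
#' @param species_map Tibble (`host_genotype`, `host_species`) or named
#'   character vector of species names named by host genotype.
#' @return Tibble (`host_species`, `host_genotype`, `strain_id`, `epc`).
#' @export
pool_species <- function(epc_summary, species_map) {
  check_columns(epc_summary, c("host_genotype", "strain_id", "epc_mean"), "epc_summary")
  if (is.character(species_map) && !is.null(names(species_map))) {
    species_map <- tibble(host_genotype = names(species_map),
                          host_species = unname(species_map))
  }
  check_columns(species_map, c("host_genotype", "host_species"), "species_map")
  unmapped <- setdiff(unique(epc_summary$host_genotype), species_map$host_genotype)
  if (length(unmapped))
    abort(sprintf("unmapped cultivar(s): %s", paste(unmapped, collapse = ", ")))
  epc_summary |>
    inner_join(species_map, by = "host_genotype") |>
    transmute(.data$host_species, .data$host_genotype, .data$strain_id,
              epc = .data$epc_mean)
}

#' Test EPC against a strain classification, per host scope
#'
#' Tables-style machinery: for each scope (host genotype or species pool),
#' runs a Kruskal-Wallis test of the EPC values across the levels of a strain
#' factor and, when three or more levels are present, the Dunn post hoc with
#' compact letters.
#'
#' @param obs Tibble of observations with a scope column, `strain_id`, and a
#'   value column.
#' @param metadata Tibble with `strain_id` and the factor column.
#' @param factor Name of the metadata column to test (e.g. `"nod_type"`).
#' @param value Name of the value column in `obs` (default `"epc_mean"`).
#' @param scope Name of the scope column (default `"host_genotype"`).
#' @param alpha Significance level for letters.
#' @return Tibble with one row per scope: `scope`, `factor`, `statistic`,
#'   `p_value`, `n`, and list columns `levels` (medians/sizes) and `letters`.
#' @export
associate_factor <- function(obs, metadata, factor, value = "epc_mean",
                             scope = "host_genotype", alpha = 0.05) {
  check_columns(obs, c(scope, "strain_id", value), "obs")
  check_columns(metadata, c("strain_id", factor), "metadata")
  df <- obs |> inner_join(metadata |> select("strain_id", all_of(factor)),
                          by = "strain_id")
  purrr::map_dfr(unique(df[[scope]]), function(sc) {
    sub <- df[df[[scope]] == sc, , drop = FALSE]
    vals <- sub[[value]]; grp <- sub[[factor]]
    kw <- kruskal_wallis(vals, grp)
    letters_tbl <- if (nlevels(droplevels(as.factor(grp))) >= 3)
      dunn_posthoc(vals, grp, alpha = alpha)$letters else NULL
    tibble(scope = sc, factor = factor, statistic = kw$statistic,
           p_value = kw$p_value, n = kw$n,
           levels = list(kw$groups), letters = list(letters_tbl))
  })
}

#' Rank strains by mean EPC in one host
#'
#' Descending by mean EPC; ties broken by total reads (when supplied), then
#' by strain label.
#'
#' @param epc_summary Tibble (`host_genotype`, `strain_id`, `epc_mean`).
#' @param host Host genotype to rank in.
#' @param counts Optional long count table for the tie-break.
#' @return Tibble of the host's strains in rank order.
#' @export
rank_strains <- function(epc_summary, host, counts = NULL) {
  check_columns(epc_summary, c("host_genotype", "strain_id", "epc_mean"), "epc_summary")
  sub <- epc_summary |> filter(.data$host_genotype == host)
  if (nrow(sub) == 0) abort(sprintf("host %s not present", host))
  if (!is.null(counts)) {
    tot <- counts |> group_by(.data$strain_id) |>
      summarise(total_reads = sum(.data$count), .groups = "drop")
    sub <- left_join(sub, tot, by = "strain_id")
  } else sub$total_reads <- 0
  sub |>
    mutate(total_reads = tidyr::replace_na(.data$total_reads, 0)) |>
    arrange(desc(.data$epc_mean), desc(.data$total_reads), .data$strain_id)
}

as_presence_matrix <- function(presence) {
  if (is.matrix(presence)) return(presence)
  if (inherits(presence, "synthetic_pangenome")) return(presence$presence_matrix)
  check_columns(presence, c("strain_id", "gene_id", "present"), "presence")
  wide <- presence |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "present")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$strain_id
  m
}

# Resolve presence rows for the given ids, aggregating barcode collision
# groups labeled "a+b": a group carries a gene iff every member does, lacks
# it iff none does, and is NA (ambiguous, never a candidate) when members
# disagree.
presence_rows_for <- function(pm, ids) {
  out <- matrix(NA, length(ids), ncol(pm), dimnames = list(ids, colnames(pm)))
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    if (id %in% rownames(pm)) {
      out[i, ] <- pm[id, ]
    } else if (grepl("+", id, fixed = TRUE)) {
      members <- strsplit(id, "+", fixed = TRUE)[[1]]
      missing <- setdiff(members, rownames(pm))
      if (length(missing))
        abort(sprintf("strain(s) missing from presence matrix: %s",
                      paste(missing, collapse = ", ")))
      sub <- pm[members, , drop = FALSE]
      agg <- colMeans(sub)
      out[i, ] <- ifelse(agg == 1, TRUE, ifelse(agg == 0, FALSE, NA))
    } else {
      abort(sprintf("strain(s) missing from presence matrix: %s", id))
    }
  }
  out
}

#' Contrast gene presence between top- and bottom-ranked strains
#'
#' A gene is a candidate iff it is present in every one of the `k_top`
#' highest-EPC strains and absent in every one of the `k_bottom` lowest, or
#' the reverse. The comparison can be restricted to a strain subset first
#' (e.g. only nodX carriers).
#'
#' @param ranked Tibble from [rank_strains()] or a character vector of strain
#'   ids in descending EPC order.
#' @param presence Presence/absence: logical strains x genes matrix, long
#'   tibble, or a `synthetic_pangenome`.
#' @param k_top,k_bottom Contrast set sizes (defaults 5; 4 also standard).
#' @param restrict_to Optional character vector of strain ids to restrict
#'   the ranking to before taking top and bottom sets.
#' @return Tibble (`gene_id`, `direction`, `top_strains`, `bottom_strains`)
#'   with `direction` in `present_in_top` / `absent_in_top`.
#' @export
contrast_genes <- function(ranked, presence, k_top = 5, k_bottom = 5,
                           restrict_to = NULL) {
  ids <- if (is.character(ranked)) ranked else {
    check_columns(ranked, "strain_id", "ranked"); ranked$strain_id
  }
  if (!is.null(restrict_to)) ids <- ids[ids %in% restrict_to]
  if (k_top + k_bottom > length(ids))
    abort("top and bottom sets overlap: k_top + k_bottom exceeds available strains")
  pm <- presence_rows_for(as_presence_matrix(presence), ids)
  top <- ids[seq_len(k_top)]
  bottom <- ids[seq.int(length(ids) - k_bottom + 1, length(ids))]
  # ambiguous (NA) collision-group cells satisfy neither "present in all"
  # nor "absent in all", so they disqualify the gene for that direction
  csum <- function(m) colSums(m)           # NA propagates, as intended
  in_top <- !is.na(csum(pm[top, , drop = FALSE])) & csum(pm[top, , drop = FALSE]) == k_top
  no_top <- !is.na(csum(pm[top, , drop = FALSE])) & csum(pm[top, , drop = FALSE]) == 0
  in_bot <- !is.na(csum(pm[bottom, , drop = FALSE])) & csum(pm[bottom, , drop = FALSE]) == k_bottom
  no_bot <- !is.na(csum(pm[bottom, , drop = FALSE])) & csum(pm[bottom, , drop = FALSE]) == 0
  cand <- tibble(gene_id = colnames(pm),
                 direction = dplyr::case_when(
                   in_top & no_bot ~ "present_in_top",
                   no_top & in_bot ~ "absent_in_top",
                   TRUE ~ NA_character_)) |>
    filter(!is.na(.data$direction))
  cand$top_strains <- list(top)
  cand$bottom_strains <- list(bottom)
  cand
}

#' Validate contrast candidates over all detected strains
#'
#' For each candidate gene, a Kruskal-Wallis test of mean EPC between
#' carriers and non-carriers over the full strain set of the host. Genes
#' fixed in all (or no) strains are flagged as undefined; single-member
#' levels run with a warning note.
#'
#' @param candidates Tibble from [contrast_genes()].
#' @param epc_summary Tibble (`host_genotype`, `strain_id`, `epc_mean`).
#' @param presence Presence/absence input (see [contrast_genes()]).
#' @param host Host genotype whose EPC values are tested.
#' @return Tibble (`gene_id`, `host`, `direction`, `statistic`, `p_value`,
#'   `n_carrier`, `n_noncarrier`, `note`).
#' @export
validate_candidates <- function(candidates, epc_summary, presence, host) {
  sub <- epc_summary |> filter(.data$host_genotype == host)
  pm <- presence_rows_for(as_presence_matrix(presence), sub$strain_id)
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    g <- candidates$gene_id[[i]]
    keep <- !is.na(pm[, g])  # ambiguous collision groups sit out this gene
    strains <- sub$strain_id[keep]
    vals <- sub$epc_mean[keep]
    carrier <- pm[strains, g] > 0
    nc <- sum(carrier); nn <- sum(!carrier)
    if (nc == 0 || nn == 0) {
      return(tibble(gene_id = g, host = host, direction = candidates$direction[[i]],
                    statistic = NA_real_, p_value = NA_real_,
                    n_carrier = nc, n_noncarrier = nn,
                    note = "fixed gene: validation undefined"))
    }
    note <- if (min(nc, nn) == 1) "single-member level" else NA_character_
    if (!is.na(note)) warn(sprintf("gene %s: %s (n = {%d, %d})", g, note, nc, nn))
    kw <- kruskal_wallis(vals, ifelse(carrier, "carrier", "noncarrier"))
    tibble(gene_id = g, host = host, direction = candidates$direction[[i]],
           statistic = kw$statistic, p_value = kw$p_value,
           n_carrier = nc, n_noncarrier = nn, note = note)
  })
}

#' Ungapped seed-and-extend local alignment
#'
#' Exact `seed_k`-mer seeding followed by two-way ungapped extension with an
#' x-drop stop (+1 match, -2 mismatch). Identity is matches over alignment
#' length; coverage is alignment length over query length. The best-scoring
#' hit is returned (ties by leftmost subject, then query, position).
#' Coordinates are 0-based half-open.
#'
#' @param query,subject DNA strings.
#' @param seed_k Exact seed length.
#' @param xdrop Score drop-off terminating extension.
#' @return One-row tibble (`score`, `identity`, `coverage`, `q_start`,
#'   `q_end`, `s_start`, `s_end`); all NA when no seed matches.
#' @export
local_align <- function(query, subject, seed_k = 11, xdrop = 20) {
  if (is.na(query) || is.na(subject) || nchar(query) == 0 || nchar(subject) == 0)
    abort("empty sequence")
  as_tibble(.seed_extend_cpp(query, subject, as.integer(seed_k), xdrop))
}

#' Is a gene present in a genome?
#'
#' TRUE iff the best [local_align()] hit strictly exceeds both the identity
#' and the coverage threshold (defaults 70%/70%, strict `>`).
#'
#' @param gene_seq,genome_seq DNA strings.
#' @param identity_threshold,coverage_threshold Fractions in (0, 1].
#' @param seed_k,xdrop Aligner parameters.
#' @return Logical scalar.
#' @export
check_presence <- function(gene_seq, genome_seq, identity_threshold = 0.70,
                           coverage_threshold = 0.70, seed_k = 11, xdrop = 20) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  hit <- local_align(gene_seq, genome_seq, seed_k = seed_k, xdrop = xdrop)
  !is.na(hit$identity) && hit$identity > identity_threshold &&
    hit$coverage > coverage_threshold
}

#' Presence/absence matrix of genes across genomes
#'
#' @param genes Named character vector of gene sequences.
#' @param genomes Named character vector of genome sequences.
#' @param identity_threshold,coverage_threshold Presence thresholds.
#' @param seed_k,xdrop Aligner parameters.
#' @return Logical strains x genes matrix with the thresholds stored as
#'   attributes.
#' @export
build_presence_matrix <- function(genes, genomes, identity_threshold = 0.70,
                                  coverage_threshold = 0.70, seed_k = 11,
                                  xdrop = 20) {
  m <- vapply(names(genes), function(g) {
    vapply(names(genomes), function(s) {
      check_presence(genes[[g]], genomes[[s]], identity_threshold,
                     coverage_threshold, seed_k, xdrop)
    }, logical(1))
  }, logical(length(genomes)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(genomes),
                                   dimnames = list(names(genomes), names(genes)))
  attr(m, "identity_threshold") <- identity_threshold
  attr(m, "coverage_threshold") <- coverage_threshold
  m
}

#' Bidirectional best hits between two gene sets
#'
#' `(a, b)` is a BBH iff `b` is `a`'s best-scoring hit in set B and `a` is
#' `b`'s best in set A (score ties broken by label order). Genes with no
#' qualifying hit stay unpaired.
#'
#' @param set_a,set_b Named character vectors of gene sequences.
#' @param seed_k,xdrop Aligner parameters.
#' @return List with `pairs` (tibble `a`, `b`, `score_ab`, `score_ba`),
#'   `unpaired_a`, `unpaired_b`.
#' @export
bidirectional_best_hits <- function(set_a, set_b, seed_k = 11, xdrop = 20) {
  if (!length(set_a) || !length(set_b)) abort("gene sets must be non-empty")
  best_hit <- function(q, targets) {
    scores <- vapply(names(targets), function(t) {
      h <- local_align(q, targets[[t]], seed_k = seed_k, xdrop = xdrop)
      if (is.na(h$score)) -Inf else h$score
    }, numeric(1))
    if (all(!is.finite(scores))) return(list(name = NA_character_, score = NA_real_))
    ord <- order(-scores, names(targets))
    list(name = names(targets)[ord[1]], score = scores[[ord[1]]])
  }
  best_ab <- purrr::map(setNames(names(set_a), names(set_a)),
                        function(a) best_hit(set_a[[a]], set_b))
  best_ba <- purrr::map(setNames(names(set_b), names(set_b)),
                        function(b) best_hit(set_b[[b]], set_a))
  pairs <- purrr::map_dfr(names(set_a), function(a) {
    b <- best_ab[[a]]$name
    if (!is.na(b) && !is.na(best_ba[[b]]$name) && best_ba[[b]]$name == a) {
      tibble(a = a, b = b, score_ab = best_ab[[a]]$score, score_ba = best_ba[[b]]$score)
    } else tibble()
  })
  list(pairs = pairs,
       unpaired_a = setdiff(names(set_a), pairs$a),
       unpaired_b = setdiff(names(set_b), pairs$b))
}
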