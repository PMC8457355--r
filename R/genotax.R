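# Genome-context classification: fragment-based ANI with genospecies
# clustering, p-distance neighbor-joining over concatenated nodulation genes
# with Nod type/group assignment, and repABC replicon (Rh group) calls.

#' Fragment-based average nucleotide identity between two genomes
#'
#' Genome A is chopped into consecutive `fragment_length`-bp fragments, each
#' locally aligned to genome B ([local_align()]); fragments are retained iff
#' their best hit has identity above `min_fragment_identity` over at least
#' `min_fragment_coverage` of the fragment. One-way ANI is the mean identity
#' of retained fragments (x100); the reported value averages both directions.
#'
#' @param genome_a,genome_b DNA strings, each at least `fragment_length` bp.
#' @param fragment_length Fragment size in bp.
#' @param min_fragment_identity,min_fragment_coverage Fragment retention
#'   thresholds.
#' @param seed_k,xdrop Aligner parameters.
#' @return One-row tibble (`ani`, `ani_ab`, `ani_ba`, `fragments_ab`,
#'   `fragments_ba`); `ani` is NA when neither direction retains a fragment.
#' @export
pairwise_ani <- function(genome_a, genome_b, fragment_length = 1020,
                         min_fragment_identity = 0.30,
                         min_fragment_coverage = 0.70,
                         seed_k = 11, xdrop = 20) {
  if (nchar(genome_a) < fragment_length || nchar(genome_b) < fragment_length)
    abort("both genomes must be at least fragment_length long")
  one_way <- function(a, b) {
    n_frag <- nchar(a) %/% fragment_length
    ids <- vapply(seq_len(n_frag), function(i) {
      frag <- substr(a, (i - 1) * fragment_length + 1, i * fragment_length)
      h <- local_align(frag, b, seed_k = seed_k, xdrop = xdrop)
      if (!is.na(h$identity) && h$identity > min_fragment_identity &&
          h$coverage >= min_fragment_coverage) h$identity else NA_real_
    }, numeric(1))
    kept <- ids[!is.na(ids)]
    list(ani = if (length(kept)) 100 * mean(kept) else NA_real_, n = length(kept))
  }
  ab <- one_way(genome_a, genome_b)
  ba <- one_way(genome_b, genome_a)
  both <- c(ab$ani, ba$ani)
  tibble(ani = if (all(is.na(both))) NA_real_ else mean(both, na.rm = TRUE),
         ani_ab = ab$ani, ani_ba = ba$ani,
         fragments_ab = ab$n, fragments_ba = ba$n)
}

#' All-pairs symmetric ANI matrix
#'
#' @param genomes Named character vector of genome sequences.
#' @param ... Passed to [pairwise_ani()].
#' @return Symmetric numeric matrix of ANI percentages with 100 on the
#'   diagonal; unalignable pairs are NA.
#' @export
ani_matrix <- function(genomes, ...) {
  n <- length(genomes)
  m <- matrix(100, n, n, dimnames = list(names(genomes), names(genomes)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      v <- pairwise_ani(genomes[[i]], genomes[[j]], ...)$ani
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m
}

#' Genospecies assignment by single-linkage ANI clustering
#'
#' Connected components of the graph with edges where ANI >= `threshold`
#' (single linkage); components are labeled `gs1, gs2, ...` by decreasing
#' size (ties by first member). Strains whose ANI to every other strain falls
#' below `outlier_threshold` are additionally flagged as outside the species
#' complex.
#'
#' @param ani Complete symmetric ANI matrix (percentages).
#' @param threshold Clustering threshold (percent ANI).
#' @param outlier_threshold Secondary threshold for the outside-complex flag.
#' @return Tibble (`strain_id`, `genospecies`, `min_within_ani`,
#'   `outside_complex`).
#' @export
assign_genospecies <- function(ani, threshold = 95, outlier_threshold = 92) {
  if (!is.matrix(ani) || nrow(ani) != ncol(ani)) abort("ani must be a square matrix")
  if (anyNA(ani)) abort("missing ANI pairs: compute all pairs first")
  if (max(abs(ani - t(ani))) > 1e-8) abort("ani must be symmetric")
  n <- nrow(ani)
  labels <- rownames(ani) %||% sprintf("S%02d", seq_len(n))
  if (n == 1) {
    return(tibble(strain_id = labels, genospecies = "gs1",
                  min_within_ani = 100, outside_complex = FALSE))
  }
  d <- as.dist(100 - ani)
  comp <- cutree(hclust(d, method = "single"), h = 100 - threshold)
  sizes <- sort(table(comp), decreasing = TRUE)
  relabel <- setNames(sprintf("gs%d", seq_along(sizes)), names(sizes))
  gs <- relabel[as.character(comp)]
  min_within <- vapply(seq_len(n), function(i) {
    members <- setdiff(which(gs == gs[[i]]), i)
    if (length(members)) min(ani[i, members]) else 100
  }, numeric(1))
  offdiag_max <- vapply(seq_len(n), function(i) max(ani[i, -i]), numeric(1))
  tibble(strain_id = labels, genospecies = unname(gs),
         min_within_ani = min_within,
         outside_complex = offdiag_max < outlier_threshold)
}

#' Pairwise p-distance of aligned sequences
#'
#' `d_ij` = mismatches / compared sites, excluding positions gapped in either
#' sequence of the pair.
#'
#' @param aligned Named character vector of equal-length aligned sequences
#'   (gaps as `-`), or a `Biostrings::DNAStringSet`.
#' @return Symmetric distance matrix.
#' @export
p_distance <- function(aligned) {
  seqs <- as_sequence_vector(aligned)
  if (length(unique(nchar(seqs))) != 1) abort("aligned sequences must be equal-length")
  if (is.null(names(seqs))) names(seqs) <- sprintf("S%02d", seq_along(seqs))
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) abort(sprintf("zero comparable sites between %s and %s",
                                  names(seqs)[i], names(seqs)[j]))
      v <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
      d[i, j] <- v; d[j, i] <- v
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (via [ape::nj()]) with validation of the input
#' and optional outgroup rooting for display.
#'
#' @param d Symmetric distance matrix with zero diagonal, n >= 3.
#' @param outgroup Optional tip label to root on.
#' @return An `ape::phylo` tree (unrooted unless `outgroup` is given).
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix must have a zero diagonal")
  if (nrow(d) < 3) abort("need at least three taxa")
  tree <- ape::nj(as.dist(d))
  if (!is.null(outgroup)) tree <- ape::root(tree, outgroup = outgroup,
                                            resolve.root = TRUE)
  tree
}

#' Assign Nod types and Nod groups from nod-gene distances
#'
#' Single-linkage clustering of the concatenated-nod-gene p-distances cut at
#' two nested thresholds: coarse clusters at `type_cut` are the Nod types
#' (A, B, ...), fine clusters at `group_cut` the Nod groups (A1, A2, ...,
#' B1, ...). Labels are ordered by decreasing cluster size. Group labels nest
#' within type labels by construction.
#'
#' @param d Symmetric p-distance matrix over strains.
#' @param type_cut,group_cut Distance cuts with `group_cut < type_cut`.
#' @return Tibble (`strain_id`, `nod_type`, `nod_group`).
#' @export
assign_nod_groups <- function(d, type_cut = 0.10, group_cut = 0.03) {
  if (!(group_cut < type_cut)) abort("group_cut must be smaller than type_cut")
  if (!is.matrix(d)) d <- as.matrix(d)
  labels <- rownames(d) %||% sprintf("S%02d", seq_len(nrow(d)))
  hc <- hclust(as.dist(d), method = "single")
  types <- cutree(hc, h = type_cut)
  groups <- cutree(hc, h = group_cut)
  if (length(unique(types)) == 1)
    warn("type cut yields a single coarse cluster")
  type_order <- names(sort(table(types), decreasing = TRUE))
  type_label <- setNames(LETTERS[seq_along(type_order)], type_order)
  out <- tibble(strain_id = labels,
                nod_type = unname(type_label[as.character(types)]),
                fine = groups)
  out <- out |>
    group_by(.data$nod_type) |>
    mutate(nod_group = {
      ord <- names(sort(table(.data$fine), decreasing = TRUE))
      paste0(.data$nod_type[1], match(as.character(.data$fine), ord))
    }) |>
    ungroup() |>
    select("strain_id", "nod_type", "nod_group")
  out
}

#' Classify a replicon into an Rh group via its repABC cassette
#'
#' The best repA hit (by [local_align()] score against the labeled reference
#' set) proposes an Rh group when its identity exceeds `similarity_floor`;
#' the group is assigned only if cognate repB and repC are also present on
#' the replicon ([check_presence()]).
#'
#' @param replicon_seq Replicon DNA string.
#' @param repA_references Named character vector of repA alleles, named by Rh
#'   group.
#' @param repB_reference,repC_reference Cognate gene references.
#' @param similarity_floor Minimum repA identity for a candidate call.
#' @param identity_threshold,coverage_threshold Presence thresholds for
#'   repB/repC.
#' @return One-row tibble (`rh_group`, `repA_group`, `repA_identity`,
#'   `repB_found`, `repC_found`, `tie`, `reason`); `rh_group` is NA when
#'   unclassified.
#' @export
classify_replicon <- function(replicon_seq, repA_references,
                              repB_reference, repC_reference,
                              similarity_floor = 0.8,
                              identity_threshold = 0.70,
                              coverage_threshold = 0.70) {
  if (!length(repA_references)) abort("repA reference set must be non-empty")
  hits <- purrr::map_dfr(names(repA_references), function(g) {
    h <- local_align(repA_references[[g]], replicon_seq)
    tibble(group = g,
           score = ifelse(is.na(h$score), -Inf, h$score),
           identity = ifelse(is.na(h$identity), 0, h$identity))
  })
  hits <- hits |> arrange(desc(.data$score), .data$group)
  tie <- nrow(hits) > 1 && is.finite(hits$score[1]) && hits$score[1] == hits$score[2]
  best <- hits[1, ]
  repA_group <- if (is.finite(best$score) && best$identity > similarity_floor)
    best$group else NA_character_
  repB_found <- check_presence(repB_reference, replicon_seq,
                               identity_threshold, coverage_threshold)
  repC_found <- check_presence(repC_reference, replicon_seq,
                               identity_threshold, coverage_threshold)
  assigned <- !is.na(repA_group) && repB_found && repC_found
  reason <- if (assigned) NA_character_ else {
    paste(c(if (is.na(repA_group)) "no repA hit above similarity floor",
            if (!repB_found) "repB missing",
            if (!repC_found) "repC missing"), collapse = "; ")
  }
  tibble(rh_group = if (assigned) repA_group else NA_character_,
         repA_group = repA_group,
         repA_identity = ifelse(is.finite(best$score), best$identity, NA_real_),
         repB_found = repB_found, repC_found = repC_found,
         tie = tie, reason = reason)
}
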