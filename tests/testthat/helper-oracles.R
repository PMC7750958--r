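# Small configs and independent oracles shared across test files.

tiny_config <- function(...) {
  defaults <- list(chrom_len = rep(100000L, 2), cluster_len = 10000L, rr = 4,
                   N = 50L, n_fl = 20L, generations = 10L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Jost's D computed a second, independent way: heterozygosities written as
# explicit loops over the union allele set.
oracle_jost_d <- function(p, q) {
  alleles <- union(names(p), names(q))
  hs <- 0
  for (v in list(p, q)) {
    h <- 1
    for (a in alleles) h <- h - (if (a %in% names(v)) v[[a]] else 0)^2
    hs <- hs + h / 2
  }
  ht <- 1
  for (a in alleles) {
    pa <- if (a %in% names(p)) p[[a]] else 0
    qa <- if (a %in% names(q)) q[[a]] else 0
    ht <- ht - ((pa + qa) / 2)^2
  }
  if (1 - hs <= 0) return(0)
  max(0, (ht - hs) / (1 - hs)) * 2
}

# random allele-frequency fingerprints over a shared allele set
random_freq_matrix <- function(n_samples, n_alleles, concentration = 1) {
  g <- matrix(stats::rgamma(n_samples * n_alleles, concentration),
              nrow = n_samples)
  g <- g / rowSums(g) * 0.8  # leave room for FL
  tbl <- tibble::as_tibble(as.data.frame(g))
  names(tbl) <- sprintf("ID_%d_%d", seq_len(n_alleles) * 10,
                        seq_len(n_alleles) * 10 + 100)
  tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%d", seq_len(n_samples))), tbl)
  tbl$FL <- 1 - rowSums(tbl[, -1])
  idroute:::new_freq_matrix(
    tbl, alleles = tibble::tibble(allele = setdiff(names(tbl),
                                                   c("sample_id", "FL")),
                                  start = seq_len(n_alleles) * 10L,
                                  end = seq_len(n_alleles) * 10L + 100L))
}

# path-length (patristic) matrix of a phylo tree, ordered by given labels
tree_path_distances <- function(tree, labels) {
  d <- ape::cophenetic.phylo(tree)
  d[labels, labels]
}

# canonical form of a split given one of its sides: the side not containing
# the lexicographically smallest tip label
canon_split <- function(side, all_labels) {
  ref <- sort(all_labels)[1]
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "|")
}

# a one-individual population carrying the given insertions
single_individual <- function(ins) {
  tibble::tibble(individual = 1L, haplotype = ins$haplotype,
                 chrom = ins$chrom, pos = ins$pos, variant = ins$variant)
}
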