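#' Synthetic fingerprint tables with a stepping-stone sharing gradient
#'
#' Generates a fingerprint table emulating DeviaTE output for a chain of
#' successively invaded populations, without running the simulator: shared
#' IDs originate in one population of the chain and are carried forward with
#' an exponentially decaying frequency kernel (`exp(-distance / tau)`), so
#' later populations accumulate the IDs of their predecessors plus their own;
#' each population additionally receives private IDs. Frequencies within a
#' population are Dirichlet-distributed around the kernel (gamma noise), then
#' scaled so the total ID fraction grows along the chain from
#' `id_total_range[1]` to `id_total_range[2]`, mirroring the increase of ID
#' content in successively invaded populations. This generator is a stand-in
#' for pool-seq derived fingerprints, not a mechanistic model.
#'
#' @param n_pops Number of populations in the chain.
#' @param n_shared_ids Number of IDs shared across at least part of the chain.
#' @param n_private_ids Private IDs per population.
#' @param tau Decay length of the sharing kernel (in populations).
#' @param id_total_range Total ID frequency in the first and last population.
#' @param support_mean Mean supporting read count (counts are 2 + Poisson).
#' @param consensus_len TE consensus length for breakpoint positions.
#' @param noise_shape Gamma shape of the frequency noise (larger = less noisy).
#' @return Tibble with columns `sample_id` (`pop1..popN`), `start`, `end`,
#'   `support`, `frequency`; attribute `truth` holds the generating order.
#' @export
generate_fixture_fingerprints <- function(n_pops = 6, n_shared_ids = 40,
                                          n_private_ids = 10, tau = 2,
                                          id_total_range = c(0.1, 0.45),
                                          support_mean = 20,
                                          consensus_len = 2907,
                                          noise_shape = 20) {
  stopifnot(n_pops >= 2, n_shared_ids >= 0, n_private_ids >= 0)
  draw_bp <- function(n) {
    s <- sample.int(consensus_len - 1, n, replace = TRUE)
    len <- pmax(2, as.integer(stats::rbeta(n, 1.5, 3) * (consensus_len - 2)))
    e <- pmin(s + len, consensus_len)
    s <- pmin(s, e - 1L)
    tibble(start = as.integer(s), end = as.integer(e))
  }
  shared <- draw_bp(n_shared_ids)
  # shared IDs originate before the last deme so each reaches >= 2 populations
  shared$origin <- sort(sample.int(max(1, n_pops - 1), n_shared_ids,
                                   replace = TRUE))
  target_total <- seq(id_total_range[1], id_total_range[2],
                      length.out = n_pops)
  rows <- list()
  for (p in seq_len(n_pops)) {
    pres <- which(shared$origin <= p)
    w <- exp(-(p - shared$origin[pres]) / tau)
    w <- w * stats::rgamma(length(w), shape = noise_shape, rate = noise_shape)
    priv <- draw_bp(n_private_ids)
    wp <- 0.3 * stats::rgamma(n_private_ids, shape = noise_shape,
                              rate = noise_shape)
    freq <- c(w, wp)
    freq <- freq / sum(freq) * target_total[p]
    bp <- bind_rows(shared[pres, c("start", "end")], priv)
    rows[[p]] <- tibble(
      sample_id = sprintf("pop%d", p),
      start = bp$start, end = bp$end,
      support = 2L + stats::rpois(nrow(bp), support_mean),
      frequency = freq
    )
  }
  out <- list_rbind(rows) |>
    group_by(.data$sample_id, .data$start, .data$end) |>
    summarise(support = max(.data$support), frequency = sum(.data$frequency),
              .groups = "drop") |>
    arrange(.data$sample_id, .data$start, .data$end)
  attr(out, "truth") <- sprintf("pop%d", seq_len(n_pops))
  out
}

#' Reconstruct an invasion route from a fingerprint table
#'
#' Runs the full reconstruction pipeline: read (or take) a fingerprint table,
#' filter by read support, cluster breakpoints within a 3-bp tolerance, drop
#' population-private IDs, append the artificial all-FL reference, compute
#' the Jost's D distance matrix, build the BIONJ tree and a bootstrap
#' majority-rule consensus, and embed the samples by classical MDS.
#'
#' @param fingerprints Path to a fingerprint TSV or a fingerprint tibble.
#' @param min_support Minimum supporting reads per ID entry.
#' @param tolerance Breakpoint tolerance in bp.
#' @param drop_private Drop population-private IDs before distances.
#' @param fl_reference Append the all-FL origin sample.
#' @param bootstrap Number of bootstrap replicates for the consensus
#'   (0 skips the consensus).
#' @param collapse Support threshold below which consensus nodes collapse.
#' @param mds_k Number of MDS axes.
#' @param out_dir Optional directory; when given, writes `distance.phylip`,
#'   `bionj.nwk`, `consensus.nwk`, `mds.tsv`, `log.tsv` and a JSON run
#'   manifest.
#' @param seed Optional seed recorded in the manifest and used for the
#'   bootstrap.
#' @return An `id_reconstruction`: list with `matrix` (filtered frequency
#'   matrix), `distance`, `tree`, `consensus`, `mds`, and `log` (tibble of
#'   entity counts after each stage).
#' @export
pipeline_reconstruct <- function(fingerprints, min_support = 3, tolerance = 3,
                                 drop_private = TRUE, fl_reference = TRUE,
                                 bootstrap = 100, collapse = 0.5, mds_k = 2,
                                 out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stage <- function(what) function(e) {
    abort(sprintf("reconstruction failed at stage '%s': %s", what,
                  conditionMessage(e)))
  }
  fp <- if (is.character(fingerprints)) {
    tryCatch(read_fingerprint_table(fingerprints, min_support = min_support),
             error = stage("read"))
  } else {
    filter(as_tibble(fingerprints), .data$support >= min_support)
  }
  log <- list(tibble(stage = "support_filter", samples = length(unique(fp$sample_id)),
                     ids = nrow(fp)))
  fm <- tryCatch(cluster_breakpoints(fp, tolerance = tolerance),
                 error = stage("cluster"))
  log <- c(log, list(tibble(stage = "cluster", samples = nrow(fm),
                            ids = length(id_allele_cols(fm)))))
  if (nrow(fm) < 2) {
    abort("reconstruction failed at stage 'cluster': need at least 2 invaded samples")
  }
  if (drop_private) {
    fm <- tryCatch(drop_private_ids(fm), error = stage("drop_private"))
    log <- c(log, list(tibble(stage = "drop_private", samples = nrow(fm),
                              ids = length(id_allele_cols(fm)))))
  }
  if (fl_reference) {
    fm <- tryCatch(add_fl_reference(fm), error = stage("fl_reference"))
  }
  if (nrow(fm) < 3) {
    abort("reconstruction failed at stage 'distance': need at least 3 samples")
  }
  d <- tryCatch(distance_matrix(fm), error = stage("distance"))
  tr <- tryCatch(bionj_tree(d), error = stage("bionj"))
  cons <- NULL
  if (bootstrap > 0 && length(id_allele_cols(fm)) >= 2 && nrow(fm) >= 4) {
    cons <- tryCatch(bootstrap_consensus(fm, B = bootstrap,
                                         threshold = collapse),
                     error = stage("consensus"))
  }
  mds <- tryCatch(classical_mds(d, k = mds_k), error = stage("mds"))
  res <- structure(
    list(matrix = fm, distance = d, tree = tr, consensus = cons, mds = mds,
         log = list_rbind(log)),
    class = "id_reconstruction"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phylip_square(d, file.path(out_dir, "distance.phylip"))
    ape::write.tree(tr, file.path(out_dir, "bionj.nwk"))
    if (!is.null(cons)) ape::write.tree(cons, file.path(out_dir, "consensus.nwk"))
    readr::write_tsv(mds, file.path(out_dir, "mds.tsv"))
    readr::write_tsv(res$log, file.path(out_dir, "log.tsv"))
    write_run_manifest(
      file.path(out_dir, "manifest.json"),
      params = list(min_support = min_support, tolerance = tolerance,
                    drop_private = drop_private, fl_reference = fl_reference,
                    bootstrap = bootstrap, collapse = collapse, mds_k = mds_k),
      seed = seed,
      outputs = c("distance.phylip", "bionj.nwk",
                  if (!is.null(cons)) "consensus.nwk", "mds.tsv", "log.tsv")
    )
  }
  res
}

#' @export
print.id_reconstruction <- function(x, ...) {
  cat(sprintf("<id_reconstruction> %d samples, %d ID alleles used\n",
              nrow(x$matrix), length(id_allele_cols(x$matrix))))
  print(x$log)
  invisible(x)
}

#' Evaluate reconstructed trees against the expected invasion route
#'
#' Counts the splits each observed tree shares with the expected caterpillar
#' and summarizes recovery with the conjugate Beta posterior
#' ([split_share_posterior()]), with `n_max = n_tips - 3`.
#'
#' @param trees A `phylo` tree or list of trees (e.g. `multiPhylo`).
#' @param expected The expected invasion tree ([expected_invasion_tree()]).
#' @return A `split_posterior` with attribute `shared_counts`.
#' @export
evaluate_route_recovery <- function(trees, expected) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  n_max <- length(expected$tip.label) - 3
  counts <- vapply(trees, shared_splits, integer(1), t2 = expected)
  post <- split_share_posterior(counts, n_max = n_max)
  attr(post, "shared_counts") <- counts
  post
}

# --- plain-format IO ---------------------------------------------------------

#' Read and write square PHYLIP distance matrices
#'
#' Square PHYLIP layout: first line the number of taxa, then one line per
#' taxon with its label and the full row of distances (whitespace separated;
#' full labels, not truncated to 10 characters).
#'
#' @param d Labelled symmetric matrix.
#' @param path File path.
#' @return `read_phylip_square()` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_phylip_square <- function(d, path) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(rownames(d)[i], sprintf("%.9f", d[i, ])), collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_square
#' @export
read_phylip_square <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) abort(sprintf("%s: empty file", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) abort(sprintf("%s:1: expected taxon count", path))
  if (length(lines) < n + 1) {
    abort(sprintf("%s: expected %d taxon lines, found %d", path, n,
                  length(lines) - 1))
  }
  labs <- character(n)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != n + 1) {
      abort(sprintf("%s:%d: expected label plus %d distances, found %d fields",
                    path, i + 1, n, length(parts)))
    }
    labs[i] <- parts[1]
    row <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(row))) abort(sprintf("%s:%d: non-numeric distance", path, i + 1))
    d[i, ] <- row
  }
  dimnames(d) <- list(labs, labs)
  d
}

#' Read and write Newick trees
#'
#' Wrappers over \pkg{ape}'s Newick parser/serializer; branch lengths keep 6
#' significant digits and internal node labels (bootstrap supports) survive
#' the round trip.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)), error = function(e) {
    abort(sprintf("%s: not a parsable Newick file (%s)", path,
                  conditionMessage(e)))
  })
  if (is.null(tr)) abort(sprintf("%s: not a parsable Newick file", path))
  tr
}

write_run_manifest <- function(path, params, seed, outputs) {
  manifest <- list(
    package = "idroute",
    version = as.character(utils::packageVersion("idroute")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
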