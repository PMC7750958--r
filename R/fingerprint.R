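#' Read an ID fingerprint table
#'
#' Reads a DeviaTE-style tab-separated fingerprint table with the columns
#' `sample_id`, `start`, `end`, `support`, `frequency` (header line required,
#' `#` comment lines allowed). Entries supported by fewer than `min_support`
#' reads are dropped, mirroring the read-support filter applied to split-read
#' evidence (2 reads for experimental, 3 for natural populations).
#'
#' @param path Path to the TSV file.
#' @param min_support Minimum supporting read count per entry.
#' @return Tibble with columns `sample_id`, `start`, `end`, `support`,
#'   `frequency`, one row per retained ID entry.
#' @export
read_fingerprint_table <- function(path, min_support = 0) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("sample_id", "start", "end", "support", "frequency")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("fingerprint table %s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(sample_id = character(), start = integer(), end = integer(),
                  support = integer(), frequency = double()))
  }
  num <- function(col, type) suppressWarnings(type(raw[[col]]))
  parsed <- tibble(
    sample_id = raw$sample_id,
    start = num("start", as.integer),
    end = num("end", as.integer),
    support = num("support", as.integer),
    frequency = num("frequency", as.double),
    line = seq_len(nrow(raw))
  )
  bad <- which(is.na(parsed$start) | is.na(parsed$end) |
                 is.na(parsed$support) | is.na(parsed$frequency))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric fields in fingerprint table at data row(s) %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(parsed$start >= parsed$end | parsed$start < 1)
  if (length(bad) > 0) {
    abort(sprintf("invalid breakpoints (need 1 <= start < end) at data row(s) %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(parsed$frequency < 0 | parsed$frequency > 1 | parsed$support < 0)
  if (length(bad) > 0) {
    abort(sprintf("frequency outside [0, 1] or negative support at data row(s) %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  parsed |>
    filter(.data$support >= min_support) |>
    select(-"line") |>
    arrange(.data$sample_id, .data$start, .data$end)
}

#' @rdname read_fingerprint_table
#' @param fingerprints Tibble of fingerprint entries as returned by
#'   [read_fingerprint_table()] or [fingerprint_table()].
#' @export
write_fingerprint_table <- function(fingerprints, path) {
  readr::write_tsv(fingerprints[, c("sample_id", "start", "end", "support",
                                    "frequency")], path)
  invisible(path)
}

#' Full-length frequency of one fingerprint
#'
#' The FL insertion is the complement of all IDs at the single TE "locus":
#' its frequency is `1 - sum(f_i)` over the ID frequencies `f_i`.
#'
#' @param fingerprint Tibble of one sample's ID entries (column `frequency`).
#' @return The FL frequency, clipped into `[0, 1]` within numerical tolerance.
#' @export
fl_frequency <- function(fingerprint) {
  s <- sum(fingerprint$frequency)
  if (s > 1 + 1e-9) {
    abort(sprintf("inconsistent fingerprint: ID frequencies sum to %.6g > 1", s))
  }
  min(max(1 - s, 0), 1)
}

#' Cluster ID breakpoints across samples into shared alleles
#'
#' IDs reported from different samples are merged into one allele when both
#' breakpoints lie within `tolerance` bp of a cluster representative (split
#' alignments place gaps ambiguously, so identical deletions can differ by a
#' few bp between samples). Representatives are chosen greedily in decreasing
#' order of total read support (ties broken by smallest `(start, end)`); an
#' entry joins the first representative with `|dstart| <= tolerance` and
#' `|dend| <= tolerance`, otherwise it becomes a new representative. Entries
#' of one sample merged into the same allele sum their frequencies.
#'
#' @param fingerprints Tibble of fingerprint entries (columns `sample_id`,
#'   `start`, `end`, `support`, `frequency`).
#' @param tolerance Breakpoint tolerance in bp (default 3).
#' @return A frequency matrix: tibble with one row per sample, one column per
#'   ID allele (named `ID_<start>_<end>` after the representative) and a
#'   final `FL` column holding `1 - rowSums(ID columns)`, so every row sums
#'   to 1. Carries attribute `alleles`, a tibble of representative
#'   breakpoints.
#' @examples
#' fp <- tibble::tibble(
#'   sample_id = c("a", "b"), start = c(808L, 810L), end = c(2560L, 2561L),
#'   support = c(10L, 8L), frequency = c(0.4, 0.3)
#' )
#' cluster_breakpoints(fp, tolerance = 3)
#' @export
cluster_breakpoints <- function(fingerprints, tolerance = 3) {
  stopifnot(tolerance >= 0)
  fp <- as_tibble(fingerprints)
  samples <- unique(fp$sample_id)
  if (nrow(fp) == 0) {
    out <- tibble(sample_id = samples, FL = rep(1, length(samples)))
    return(new_freq_matrix(out, alleles = tibble(allele = character(),
                                                 start = integer(),
                                                 end = integer())))
  }
  key <- fp |>
    group_by(.data$start, .data$end) |>
    summarise(total_support = sum(.data$support), .groups = "drop") |>
    arrange(dplyr::desc(.data$total_support), .data$start, .data$end)
  rep_start <- integer(0)
  rep_end <- integer(0)
  assign_idx <- integer(nrow(key))
  for (i in seq_len(nrow(key))) {
    hit <- which(abs(rep_start - key$start[i]) <= tolerance &
                   abs(rep_end - key$end[i]) <= tolerance)
    if (length(hit) > 0) {
      assign_idx[i] <- hit[1]
    } else {
      rep_start <- c(rep_start, key$start[i])
      rep_end <- c(rep_end, key$end[i])
      assign_idx[i] <- length(rep_start)
    }
  }
  key$allele <- sprintf("ID_%d_%d", rep_start[assign_idx], rep_end[assign_idx])
  alleles <- tibble(allele = sprintf("ID_%d_%d", rep_start, rep_end),
                    start = rep_start, end = rep_end)
  wide <- fp |>
    left_join(key[, c("start", "end", "allele")], by = c("start", "end")) |>
    group_by(.data$sample_id, .data$allele) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "allele", values_from = "frequency",
                       values_fill = 0)
  # keep allele columns in representative order
  wide <- wide[, c("sample_id", intersect(alleles$allele, names(wide)))]
  id_sum <- rowSums(wide[, -1, drop = FALSE])
  if (any(id_sum > 1 + 1e-9)) {
    abort("ID frequencies of a sample sum to > 1 after clustering")
  }
  wide$FL <- pmin(pmax(1 - id_sum, 0), 1)
  new_freq_matrix(wide, alleles = alleles)
}

new_freq_matrix <- function(tbl, alleles, private_dropped = FALSE,
                            fl_ref = FALSE) {
  structure(tbl, class = c("freq_matrix", class(tbl)),
            alleles = alleles, private_dropped = private_dropped,
            fl_ref = fl_ref)
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("<freq_matrix> %d sample(s) x %d ID allele(s)%s%s\n", nrow(x),
              ncol(x) - 2, if (attr(x, "private_dropped")) ", private IDs dropped" else "",
              if (attr(x, "fl_ref")) ", FL reference added" else ""))
  NextMethod()
}

id_allele_cols <- function(matrix) {
  setdiff(names(matrix), c("sample_id", "FL"))
}

#' Drop population-private ID alleles
#'
#' Removes ID alleles with nonzero frequency in exactly one sample. Private
#' IDs are abundant (they arise during each population's own invasion) and
#' add noise to between-population distances, so they are excluded before
#' PCA and Jost's D. The FL column is recomputed as `1 -` the sum of the
#' retained ID frequencies, keeping each row a probability vector.
#'
#' @param matrix A frequency matrix from [cluster_breakpoints()].
#' @return The filtered frequency matrix.
#' @export
drop_private_ids <- function(matrix) {
  if (nrow(matrix) < 2) abort("need at least two samples to define private IDs")
  ids <- id_allele_cols(matrix)
  n_occ <- vapply(ids, function(a) sum(matrix[[a]] > 0), integer(1))
  keep <- ids[n_occ != 1]
  out <- matrix[, c("sample_id", keep)]
  id_sum <- if (length(keep)) rowSums(out[, keep, drop = FALSE]) else rep(0, nrow(out))
  out$FL <- pmin(pmax(1 - id_sum, 0), 1)
  alleles <- attr(matrix, "alleles")
  new_freq_matrix(out, alleles = alleles[alleles$allele %in% keep, ,
                                         drop = FALSE],
                  private_dropped = TRUE, fl_ref = attr(matrix, "fl_ref"))
}

#' Append an artificial all-FL reference sample
#'
#' Adds one sample consisting solely of FL elements (`FL = 1`, all IDs 0).
#' Placed among invaded populations it marks the putative origin of the
#' invasion, since early-invaded populations retain the most FL copies.
#'
#' @param matrix A frequency matrix.
#' @param label Sample id of the reference row (default `"FL"`).
#' @return The frequency matrix with one extra row.
#' @export
add_fl_reference <- function(matrix, label = "FL") {
  if (label %in% matrix$sample_id) {
    abort(sprintf("sample id '%s' already present", label))
  }
  ids <- id_allele_cols(matrix)
  row <- as_tibble(c(list(sample_id = label),
                     stats::setNames(as.list(rep(0, length(ids))), ids),
                     list(FL = 1)))
  new_freq_matrix(bind_rows(matrix, row), alleles = attr(matrix, "alleles"),
                  private_dropped = attr(matrix, "private_dropped"),
                  fl_ref = TRUE)
}

#' Jost's D between two allele-frequency vectors
#'
#' Computes Jost's differentiation measure D for two demes from allele
#' frequencies: with `H_S` the mean within-sample heterozygosity
#' `1 - sum(p_i^2)`, and `H_T` the heterozygosity of the pooled frequencies
#' `(p + q) / 2`, `D = (H_T - H_S) / (1 - H_S) * n / (n - 1)` with `n = 2`
#' demes. Unlike Fst-type measures, D is unbiased when one locus carries many
#' alleles, which is exactly the situation of a TE "locus" whose alleles are
#' the distinct IDs plus FL.
#'
#' @param p,q Named numeric vectors of allele frequencies, each summing to 1.
#' @return D in `[0, 1]`.
#' @examples
#' jost_d_pair(c(FL = 0.8, id1 = 0.2), c(FL = 0.4, id1 = 0.6))  # 0.2667
#' @export
jost_d_pair <- function(p, q) {
  for (v in list(p, q)) {
    if (abs(sum(v) - 1) > 1e-6) {
      abort("allele frequencies must sum to 1 (within 1e-6)")
    }
  }
  alleles <- union(names(p), names(q))
  if (is.null(names(p)) || is.null(names(q))) {
    if (length(p) != length(q)) abort("unnamed frequency vectors must align")
    pp <- p
    qq <- q
  } else {
    pp <- stats::setNames(rep(0, length(alleles)), alleles)
    qq <- pp
    pp[names(p)] <- p
    qq[names(q)] <- q
  }
  h_s <- mean(c(1 - sum(pp^2), 1 - sum(qq^2)))
  h_t <- 1 - sum(((pp + qq) / 2)^2)
  if (1 - h_s <= 0) return(0)
  if (h_t <= h_s) return(0)
  min(1, (h_t - h_s) / (1 - h_s) * 2)
}

#' Pairwise Jost's D distance matrix
#'
#' @param matrix A frequency matrix (rows summing to 1 over ID alleles + FL).
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   `sample_id`.
#' @export
distance_matrix <- function(matrix) {
  if (nrow(matrix) < 3) abort("need at least 3 samples for a useful distance matrix")
  cols <- c(id_allele_cols(matrix), "FL")
  m <- as.matrix(matrix[, cols])
  rownames(m) <- matrix$sample_id
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- jost_d_pair(m[i, ], m[j, ])
    }
  }
  d
}

#' Shared and private IDs between two fingerprints
#'
#' Matches the IDs of two samples one-to-one, closest pairs first, counting a
#' pair as shared when both breakpoints agree within `tolerance` bp.
#'
#' @param finger_a,finger_b Tibbles of ID entries (columns `start`, `end`).
#' @param tolerance Breakpoint tolerance in bp.
#' @return Named integer vector: `shared`, `unique_a`, `unique_b`.
#' @export
id_overlap <- function(finger_a, finger_b, tolerance = 3) {
  a <- as_tibble(finger_a)
  b <- as_tibble(finger_b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(c(shared = 0L, unique_a = nrow(a), unique_b = nrow(b)))
  }
  cand <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b))) |>
    mutate(ds = abs(a$start[.data$i] - b$start[.data$j]),
           de = abs(a$end[.data$i] - b$end[.data$j])) |>
    filter(.data$ds <= tolerance, .data$de <= tolerance) |>
    arrange(.data$ds + .data$de)
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  shared <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]
    j <- cand$j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- used_b[j] <- TRUE
      shared <- shared + 1L
    }
  }
  c(shared = shared, unique_a = sum(!used_a), unique_b = sum(!used_b))
}
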