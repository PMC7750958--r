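test_that("fingerprint tables round-trip and enforce the support filter", {
  fp <- tibble::tibble(
    sample_id = c("a", "a", "a", "b", "b"),
    start = c(100L, 500L, 808L, 102L, 810L),
    end = c(200L, 900L, 2560L, 198L, 2561L),
    support = c(1L, 5L, 10L, 3L, 8L),
    frequency = c(0.05, 0.2, 0.4, 0.1, 0.35)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprint_table(fp, path)
  back <- read_fingerprint_table(path, min_support = 0)
  expect_equal(dplyr::arrange(back, sample_id, start),
               dplyr::arrange(fp, sample_id, start))

  filtered <- read_fingerprint_table(path, min_support = 2)
  expect_equal(nrow(filtered), 4)              # the support-1 entry is dropped
  expect_false(any(filtered$support < 2))

  # 5 rows across 2 samples all passing -> 2 samples, 5 entries
  all_in <- read_fingerprint_table(path, min_support = 1)
  expect_equal(length(unique(all_in$sample_id)), 2)
  expect_equal(nrow(all_in), 5)

  # empty file (header only)
  empty_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tstart\tend\tsupport\tfrequency", empty_path)
  expect_equal(nrow(read_fingerprint_table(empty_path)), 0)

  # malformed input names the offending place
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tstart\tend\tsupport\tfrequency",
               "a\t500\t200\t3\t0.1"), bad)
  expect_error(read_fingerprint_table(bad), "row")
  writeLines(c("sample_id\tstart\tend", "a\t1\t2"), bad)
  expect_error(read_fingerprint_table(bad), "missing column")
  writeLines(c("sample_id\tstart\tend\tsupport\tfrequency",
               "a\tx\t200\t3\t0.1"), bad)
  expect_error(read_fingerprint_table(bad), "non-numeric")
})

test_that("breakpoint clustering merges within tolerance against representatives", {
  fp <- tibble::tibble(
    sample_id = c("A", "B"), start = c(808L, 810L), end = c(2560L, 2561L),
    support = c(10L, 8L), frequency = c(0.4, 0.3)
  )
  fm <- cluster_breakpoints(fp, tolerance = 3)
  expect_equal(id_allele_cols <- setdiff(names(fm), c("sample_id", "FL")),
               "ID_808_2560")                  # one shared allele, rep = higher support
  expect_equal(fm$ID_808_2560, c(0.4, 0.3))
  expect_equal(fm$FL, c(0.6, 0.7))

  # dstart = 4 exceeds the tolerance: two alleles
  fp2 <- tibble::tibble(sample_id = c("A", "B"), start = c(808L, 812L),
                        end = c(2560L, 2560L), support = c(5L, 5L),
                        frequency = c(0.2, 0.2))
  fm2 <- cluster_breakpoints(fp2, tolerance = 3)
  expect_equal(length(setdiff(names(fm2), c("sample_id", "FL"))), 2)

  # chains do not merge transitively: only entries within tolerance of the
  # representative itself join it
  fp3 <- tibble::tibble(
    sample_id = c("A", "B", "C"),
    start = c(100L, 103L, 106L), end = c(200L, 203L, 206L),
    support = c(9L, 5L, 3L), frequency = c(0.1, 0.1, 0.1)
  )
  fm3 <- cluster_breakpoints(fp3, tolerance = 3)
  alleles <- setdiff(names(fm3), c("sample_id", "FL"))
  expect_setequal(alleles, c("ID_100_200", "ID_106_206"))

  # within-sample merged entries sum their frequencies
  fp4 <- tibble::tibble(sample_id = "A", start = c(100L, 101L),
                        end = c(200L, 201L), support = c(5L, 4L),
                        frequency = c(0.1, 0.15))
  fm4 <- cluster_breakpoints(fp4, tolerance = 3)
  expect_equal(fm4$ID_100_200, 0.25)

  # tolerance 0 is the identity grouping on exact breakpoints
  fm0 <- cluster_breakpoints(fp3, tolerance = 0)
  expect_equal(length(setdiff(names(fm0), c("sample_id", "FL"))), 3)

  # rows always sum to 1
  for (m in list(fm, fm2, fm3, fm4, fm0)) {
    expect_equal(rowSums(m[, setdiff(names(m), "sample_id")]),
                 rep(1, nrow(m)), ignore_attr = TRUE)
  }
})

test_that("FL frequency is the complement of the ID frequencies", {
  expect_equal(fl_frequency(tibble::tibble(frequency = c(0.3, 0.2))), 0.5)
  expect_equal(fl_frequency(tibble::tibble(frequency = double())), 1)
  expect_error(fl_frequency(tibble::tibble(frequency = c(0.6, 0.5))),
               "inconsistent")
})

test_that("private-ID exclusion keeps rows on the probability simplex", {
  fp <- tibble::tibble(
    sample_id = rep(c("a", "b", "c"), times = c(3, 2, 1)),
    start = c(100L, 300L, 500L, 100L, 300L, 700L),
    end = c(200L, 400L, 600L, 200L, 400L, 800L),
    support = 5L,
    frequency = c(0.2, 0.1, 0.3, 0.25, 0.15, 0.4)
  )
  fm <- cluster_breakpoints(fp, tolerance = 3)
  dropped <- drop_private_ids(fm)
  kept <- setdiff(names(dropped), c("sample_id", "FL"))
  expect_setequal(kept, c("ID_100_200", "ID_300_400"))  # 500-600 and 700-800 private
  expect_equal(rowSums(dropped[, -1]), rep(1, 3), ignore_attr = TRUE)
  expect_equal(dropped$FL[1], 1 - 0.2 - 0.1)

  # degenerate: everything private collapses to an FL-only matrix
  all_priv <- tibble::tibble(
    sample_id = c("a", "b"), start = c(100L, 700L), end = c(200L, 800L),
    support = 5L, frequency = c(0.2, 0.3)
  )
  flonly <- drop_private_ids(cluster_breakpoints(all_priv, 3))
  expect_equal(setdiff(names(flonly), c("sample_id", "FL")), character(0))
  expect_equal(flonly$FL, c(1, 1))
})

test_that("the artificial FL reference is a pure-FL sample", {
  fm <- random_freq_matrix(4, 6)
  with_ref <- add_fl_reference(fm)
  expect_equal(nrow(with_ref), 5)
  ref <- with_ref[with_ref$sample_id == "FL", ]
  expect_equal(ref$FL, 1)
  expect_true(all(ref[, setdiff(names(ref), c("sample_id", "FL"))] == 0))
  expect_error(add_fl_reference(with_ref), "already present")

  # FL reference is at distance zero from an all-FL sample
  p_ref <- c(FL = 1)
  expect_equal(jost_d_pair(p_ref, c(FL = 1)), 0)
})

test_that("Jost's D matches the two-deme formula and its invariants", {
  # hand-evaluated case: H_S = 0.40, H_T = 0.48, D = (0.08 / 0.60) * 2
  expect_lt(abs(jost_d_pair(c(FL = 0.8, id1 = 0.2), c(FL = 0.4, id1 = 0.6)) -
                  0.2667), 1e-4)
  expect_equal(jost_d_pair(c(id1 = 1), c(id2 = 1)), 1)       # disjoint alleles
  expect_equal(jost_d_pair(c(id1 = 0.5, id2 = 0.5), c(id1 = 0.5, id2 = 0.5)), 0)
  expect_equal(jost_d_pair(c(FL = 1), c(FL = 1)), 0)         # both monomorphic
  expect_error(jost_d_pair(c(FL = 0.5), c(FL = 1)), "sum to 1")

  set.seed(20)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    p <- stats::setNames(as.vector(stats::rgamma(k, 1)), paste0("a", 1:k))
    q <- stats::setNames(as.vector(stats::rgamma(k, 1)), paste0("a", sample(1:7, k)))
    p <- p / sum(p)
    q <- q / sum(q)
    d <- jost_d_pair(p, q)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, jost_d_pair(q, p))            # symmetric
    expect_equal(d, oracle_jost_d(as.list(p), as.list(q)), tolerance = 1e-12)
  }
})

test_that("the distance matrix agrees with element-wise recomputation", {
  set.seed(21)
  fm <- random_freq_matrix(5, 8)
  d <- distance_matrix(fm)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 5), ignore_attr = TRUE)
  cols <- setdiff(names(fm), "sample_id")
  for (i in 1:4) {
    for (j in (i + 1):5) {
      p <- stats::setNames(as.numeric(fm[i, cols]), cols)
      q <- stats::setNames(as.numeric(fm[j, cols]), cols)
      expect_equal(d[i, j], oracle_jost_d(as.list(p), as.list(q)),
                   tolerance = 1e-12)
    }
  }

  # duplicated samples sit at distance zero
  dup <- fm
  dup[2, -1] <- dup[1, -1]
  expect_equal(distance_matrix(dup)[1, 2], 0)

  # three mutually disjoint single-allele samples are all at distance 1
  tri <- idroute:::new_freq_matrix(
    tibble::tibble(sample_id = c("x", "y", "z"),
                   ID_1_10 = c(1, 0, 0), ID_2_20 = c(0, 1, 0),
                   ID_3_30 = c(0, 0, 1), FL = c(0, 0, 0)),
    alleles = tibble::tibble(allele = c("ID_1_10", "ID_2_20", "ID_3_30"),
                             start = 1:3, end = c(10L, 20L, 30L)))
  d3 <- distance_matrix(tri)
  expect_equal(d3[upper.tri(d3)], rep(1, 3))
})

test_that("ID overlap counts shared breakpoint pairs one-to-one", {
  a <- tibble::tibble(start = c(100L, 500L), end = c(200L, 900L))
  b <- tibble::tibble(start = 102L, end = 198L)
  expect_equal(id_overlap(a, b, tolerance = 3),
               c(shared = 1L, unique_a = 1L, unique_b = 0L))
  expect_equal(id_overlap(a, a, tolerance = 0),
               c(shared = 2L, unique_a = 0L, unique_b = 0L))
  far <- tibble::tibble(start = 300L, end = 400L)
  expect_equal(id_overlap(a, far, tolerance = 3)[["shared"]], 0L)
  expect_equal(id_overlap(a, a[0, ], tolerance = 3)[["unique_a"]], 2L)
})
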