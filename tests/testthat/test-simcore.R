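test_that("population initialization places FL copies at distinct sites, one per haplotype", {
  cfg <- tiny_config()
  set.seed(1)
  empty <- init_population(cfg, n_fl = 0)
  expect_equal(nrow(empty$insertions), 0)
  expect_error(population_fingerprint(empty), "no TE copies")

  pop <- init_population(sim_config(N = 1000), n_fl = 250)
  ins <- pop$insertions
  expect_equal(nrow(ins), 250)               # copy conservation
  expect_true(all(ins$variant == 0))         # all FL
  expect_equal(nrow(dplyr::distinct(ins, chrom, pos)), 250)  # distinct sites
  # each copy sits on exactly one haplotype of one individual: frequency 1/2N
  expect_equal(max(table(paste(ins$individual, ins$haplotype, ins$chrom, ins$pos))), 1)
  expect_error(init_population(tiny_config(), n_fl = 300000), "sites")
})

test_that("trap-model activity needs an FL copy and a cluster-free genome", {
  cfg <- tiny_config()  # chrom 100 kb, cluster = last 10 kb
  fl_outside <- tibble::tibble(haplotype = 1L, chrom = 1L, pos = 5000L, variant = 0L)
  id_inside <- tibble::tibble(haplotype = 2L, chrom = 2L, pos = 95000L, variant = 1L)
  id_outside <- tibble::tibble(haplotype = 1L, chrom = 2L, pos = 1000L, variant = 2L)

  expect_true(is_active(fl_outside, cfg))                       # 1 FL, no cluster
  expect_false(is_active(id_outside, cfg))                      # no FL at all
  expect_false(is_active(dplyr::bind_rows(fl_outside, fl_outside |>
    dplyr::mutate(pos = 6000L), fl_outside |> dplyr::mutate(pos = 7000L),
    id_inside), cfg))                                           # cluster insertion silences
  # boundary: cluster occupies the last cluster_len bp inclusive
  at_boundary <- tibble::tibble(haplotype = 1L, chrom = 1L, pos = 90000L, variant = 0L)
  just_inside <- tibble::tibble(haplotype = 1L, chrom = 1L, pos = 90001L, variant = 0L)
  expect_true(is_active(at_boundary, cfg))
  expect_false(is_active(just_inside, cfg))
})

test_that("gametes are legal mosaics of the parental haplotypes", {
  cfg0 <- tiny_config(rr = 0)
  parent <- tibble::tibble(
    haplotype = c(1L, 1L, 2L), chrom = c(1L, 1L, 2L),
    pos = c(100L, 50000L, 200L), variant = 0L
  )
  set.seed(2)
  for (i in 1:20) {
    g <- make_gamete(parent, cfg0)
    # without recombination each chromosome comes wholesale from one haplotype
    c1 <- g[g$chrom == 1, ]
    expect_true(nrow(c1) %in% c(0L, 2L))
    expect_true(nrow(g[g$chrom == 2, ]) %in% c(0L, 1L))
  }
  # homozygous parent: gamete equals the shared haplotype whatever the map
  hom <- tibble::tibble(haplotype = rep(1:2, each = 2),
                        chrom = 1L, pos = rep(c(100L, 90000L), 2), variant = 0L)
  cfg_hot <- tiny_config(rr = 100)
  set.seed(3)
  for (i in 1:20) {
    g <- make_gamete(hom, cfg_hot)
    expect_equal(g$pos, c(100L, 90000L))
  }
})

test_that("recombinant fraction between distant markers matches the Poisson map", {
  # markers at the two ends of a 100-kb chromosome, rr = 500 cM/Mb:
  # expected crossovers between them ~ Poisson(0.5), so the recombinant
  # fraction is P(odd) = (1 - exp(-1)) / 2 = 0.316
  cfg <- tiny_config(rr = 500)
  parent <- tibble::tibble(haplotype = c(1L, 1L), chrom = 1L,
                           pos = c(1L, 100000L), variant = 0L)
  set.seed(4)
  n <- 4000
  recomb <- 0
  for (i in seq_len(n)) {
    g <- make_gamete(parent, cfg)
    if (nrow(g) == 1) recomb <- recomb + 1
  }
  expected <- (1 - exp(-1)) / 2
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(recomb / n - expected), 4 * se)
})

test_that("transposition count and conversion follow the cut-and-paste model", {
  # homozygous parent with 5 sites on both haplotypes: every gamete carries 5
  # copies, so new insertions ~ Poisson(u * 5) = 0.5 on average
  cfg <- tiny_config(u = 0.1, conversion = 0)
  parent <- tibble::tibble(haplotype = rep(1:2, each = 5), chrom = 1L,
                           pos = rep(seq(1000L, 5000L, by = 1000L), 2),
                           variant = 0L)
  set.seed(5)
  gains <- replicate(4000, {
    g <- make_gamete(parent, cfg)
    res <- transpose_into_gamete(parent, g, cfg)
    nrow(res$gamete) - 5
  })
  expect_lt(abs(mean(gains) - 0.5), 4 * sqrt(0.5 / 4000))
  expect_equal(sum(gains < 0), 0)

  # conversion disabled: no ID ever arises
  set.seed(6)
  cfg_c0 <- tiny_config(u = 2, conversion = 0)
  for (i in 1:50) {
    res <- transpose_into_gamete(parent, make_gamete(parent, cfg_c0), cfg_c0)
    expect_true(all(res$gamete$variant == 0))
    expect_equal(nrow(res$variants), 0)
  }

  # forced conversion (c = 1, FL templates only): every transposition event
  # pastes a complete FL copy and converts its template in place, so the FL
  # count is invariant and the ID count equals the number of events
  set.seed(7)
  cfg_c1 <- tiny_config(u = 2, conversion = 1, fl_id = 1)
  for (i in 1:50) {
    g <- make_gamete(parent, cfg_c1)
    n_fl_before <- sum(g$variant == 0)
    res <- transpose_into_gamete(parent, g, cfg_c1)
    gained <- nrow(res$gamete) - nrow(g)
    expect_equal(sum(res$gamete$variant == 0), n_fl_before)
    expect_equal(sum(res$gamete$variant > 0), gained)
    # fresh breakpoints are legal and ordered
    if (nrow(res$variants) > 0) {
      expect_true(all(res$variants$start >= 1 &
                        res$variants$start < res$variants$end &
                        res$variants$end <= cfg_c1$consensus_len))
    }
  }

  # inactive parent (cluster insertion): gamete passes through untouched
  silenced <- dplyr::bind_rows(
    parent, tibble::tibble(haplotype = 1L, chrom = 1L, pos = 95000L, variant = 0L))
  set.seed(8)
  g <- make_gamete(silenced, cfg_c1)
  res <- transpose_into_gamete(silenced, g, cfg_c1)
  expect_equal(res$gamete, g)
})

test_that("a generation keeps N fixed and conserves copies under neutrality", {
  cfg <- tiny_config(u = 0, conversion = 0, x = 0, N = 200L, generations = 50L)
  set.seed(9)
  finals <- replicate(20, {
    run_single_invasion(cfg, seed = sample.int(1e6, 1))$records |>
      dplyr::filter(generation == 50) |>
      dplyr::pull(copy_number)
  })
  # neutral drift only: expectation stays at the initial 20 copies / 200 inds
  init_cn <- 20 / 200
  expect_lt(abs(mean(finals) - init_cn) / (sd(finals) / sqrt(20)), 3)

  pop <- init_population(cfg)
  nxt <- step_generation(pop, cfg)
  expect_lte(max(nxt$insertions$individual), cfg$N)
  expect_named(attr(nxt, "stats"),
               c("copy_number", "fraction_id", "cluster_insertions", "n_variants"))
})

test_that("a fully silenced population never gains copies and extinction errors", {
  cfg <- tiny_config(u = 2, conversion = 1, N = 30L)
  # every individual is homozygous for a cluster insertion (so every possible
  # offspring inherits one) and carries an FL copy outside the cluster
  ins <- purrr::map(1:30, function(i) {
    tibble::tibble(individual = i, haplotype = rep(1:2, each = 2),
                   chrom = 1L, pos = rep(c(5000L, 95000L), 2), variant = 0L)
  }) |> purrr::list_rbind()
  pop <- idroute:::new_te_population(as.matrix(ins),
                                     idroute:::empty_variants(), 30L)
  set.seed(10)
  total0 <- nrow(pop$insertions)
  cur <- pop
  for (g in 1:15) {
    cur <- step_generation(cur, cfg)
    expect_lte(nrow(cur$insertions), total0)      # drift can lose, never gain
    expect_equal(nrow(cur$variants), 0)            # and no ID is ever created
  }

  # all-zero fitness aborts
  cfg_lethal <- tiny_config(x = 1)
  lethal <- idroute:::new_te_population(
    as.matrix(tibble::tibble(individual = 1:50, haplotype = 1L, chrom = 1L,
                             pos = 1000L + 17L * (1:50), variant = 0L)),
    idroute:::empty_variants(), 50L)
  expect_error(step_generation(lethal, cfg_lethal), "extinct")
})

test_that("migration copies individuals and keeps both censuses at N", {
  cfg <- tiny_config(N = 40L)
  set.seed(11)
  src <- init_population(cfg, n_fl = 30)
  tgt <- init_population(cfg, n_fl = 0)

  same <- migrate(src, tgt, 0)
  expect_equal(same$source$insertions, src$insertions)
  expect_equal(same$target$insertions, tgt$insertions)

  sig <- function(p) sort(paste(p$insertions$haplotype, p$insertions$chrom,
                                p$insertions$pos, p$insertions$variant))
  moved <- migrate(src, tgt, 10)
  expect_equal(sig(moved$source), sig(src))              # source unchanged
  expect_gt(nrow(moved$target$insertions), 0)            # invasion triggered

  full <- migrate(src, tgt, 40)
  # target is a permutation of source: same multiset of genomes
  expect_equal(sig(full$target), sig(src))
  expect_error(migrate(src, tgt, 41), "exceeds")
})

test_that("identical seed and config reproduce a run bit-identically", {
  cfg <- tiny_config(u = 0.2, conversion = 0.1, generations = 30L,
                     sample_generations = c(15L, 30L))
  a <- run_single_invasion(cfg, seed = 99)
  b <- run_single_invasion(cfg, seed = 99)
  expect_identical(a$records, b$records)
  expect_identical(a$fingerprints, b$fingerprints)
  expect_identical(a$variants, b$variants)

  # conversion disabled: the ID machinery is provably inert
  c0 <- run_single_invasion(tiny_config(u = 0.3, conversion = 0,
                                        generations = 40L), seed = 3)
  expect_true(all(c0$records$fraction_id == 0, na.rm = TRUE))
  expect_equal(nrow(c0$variants), 0)
})

test_that("stepping-stone scheduling seeds populations in order", {
  cfg <- sim_config(chrom_len = rep(100000L, 2), cluster_len = 10000L,
                    N = 50L, n_fl = 20L, u = 0.2, conversion = 0.05,
                    n_pops = 3, migration_m = 10, migration_interval = 15,
                    generations = 45, record_every = 5)
  inv <- run_stepping_stone(cfg, seed = 12)
  rec <- inv$records
  # population 2 has no copies before the first migration at generation 15
  expect_true(all(rec$copy_number[rec$population == 2 & rec$generation < 15] == 0))
  expect_true(all(rec$copy_number[rec$population == 3 & rec$generation < 30] == 0))
  expect_gt(rec$copy_number[rec$population == 2 & rec$generation == 20], 0)

  # m = 0 never seeds the second population
  cfg0 <- sim_config(chrom_len = rep(100000L, 2), cluster_len = 10000L,
                     N = 50L, n_fl = 20L, n_pops = 2, migration_m = 0,
                     migration_interval = 0, generations = 30)
  inv0 <- run_invasion(cfg0, seed = 13)
  expect_true(all(inv0$records$copy_number[inv0$records$population == 2] == 0))
})

test_that("population fingerprints count ID frequencies among all copies", {
  # 75 FL + 25 copies of one ID across a small population
  ins <- dplyr::bind_rows(
    tibble::tibble(individual = rep(1:25, each = 3), haplotype = 1L, chrom = 1L,
                   pos = as.integer(1:75 * 100), variant = 0L),
    tibble::tibble(individual = rep(1:25, each = 1), haplotype = 2L, chrom = 1L,
                   pos = as.integer(76:100 * 100), variant = 1L)
  )
  pop <- idroute:::new_te_population(
    as.matrix(ins), tibble::tibble(id = 1L, start = 808L, end = 2560L), 25L)
  fp <- population_fingerprint(pop, sample_id = "x")
  expect_equal(nrow(fp), 1)
  expect_equal(fp$frequency, 0.25)
  expect_equal(fp$support, 25L)
  expect_equal(fl_frequency(fp), 0.75)

  # three IDs at 10 copies each plus 70 FL
  ins3 <- dplyr::bind_rows(
    tibble::tibble(individual = 1:35, haplotype = 1L, chrom = 1L,
                   pos = as.integer(1:35 * 10), variant = 0L),
    tibble::tibble(individual = 1:35, haplotype = 2L, chrom = 1L,
                   pos = as.integer(36:70 * 10), variant = 0L),
    tibble::tibble(individual = rep(1:10, 3), haplotype = 1L, chrom = 2L,
                   pos = as.integer(1:30 * 10),
                   variant = rep(1:3, each = 10))
  )
  pop3 <- idroute:::new_te_population(
    as.matrix(ins3),
    tibble::tibble(id = 1:3, start = c(100L, 300L, 500L),
                   end = c(200L, 400L, 600L)), 35L)
  fp3 <- population_fingerprint(pop3)
  expect_equal(sort(fp3$frequency), rep(0.1, 3))
  expect_equal(fl_frequency(fp3), 0.7)
})
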