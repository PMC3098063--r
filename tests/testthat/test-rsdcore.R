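test_that("parameter grids are Cartesian and divergence-major", {
  g <- param_grid()
  expect_length(g, 12L)
  expect_equal(vapply(g[1:4], `[[`, numeric(1), "divergence"), rep(0.2, 4))
  expect_length(param_grid(0.8, 1e-10), 1L)
  set.seed(3)
  d <- sort(runif(3, 0.1, 1)); e <- 10^-sample(2:30, 5)
  expect_length(param_grid(d, e), 15L)
  expect_error(param_setting(0, 1e-5))
  expect_error(param_setting(0.5, -1))
})

test_that("forward pass returns the smallest-distance survivor", {
  sch <- fix_scheme()
  model <- fix_jtt()
  sim <- simulate_genome_pair(sim_config(n_genes = 15, t = 0.3, seed = 101),
                              model)
  setting <- param_setting(0.5, 1e-5)
  # exact copy of the query in J wins with ~zero distance
  J2 <- format_genome(c(sim$A$seqs[1], sim$B$seqs[-1]), "Jcopy.aa")
  q <- sim$A$seqs[1]
  fw <- forward_best_hit(q, J2, setting, sch, model)
  expect_identical(fw$j_id, names(q))
  expect_lte(fw$distance, 1e-6)

  # winner equals a brute-force pass over every hit independently
  for (k in c(1, 4, 9)) {
    q <- sim$A$seqs[k]
    fw <- forward_best_hit(q, sim$B, setting, sch, model)
    hs <- local_search(q, sim$B, sch, setting$evalue, max_hits = Inf)
    dists <- c()
    for (sid in hs$hits$subject_id) {
      aln <- global_align(q, sim$B$seqs[sid], sch)
      if (alignable_fraction(aln) >= setting$divergence) {
        dists[sid] <- ml_distance(aln, model)$t_hat
      }
    }
    expect_identical(fw$j_id, names(dists)[order(dists, names(dists))][1])
    expect_equal(fw$distance, unname(min(dists)), tolerance = 1e-12)
  }
})

test_that("divergence filter can eliminate every hit", {
  sch <- fix_scheme()
  model <- fix_jtt()
  # subject genome holds only a short fragment of the query: strong local
  # hit, but the global alignment is mostly gaps
  set.seed(111)
  full <- random_protein(300)
  frag <- substr(full, 1, 90)
  J <- format_genome(c(frag1 = frag), "Frag.aa")
  aln <- global_align(c(q = full), c(frag1 = frag), sch)
  expect_lt(alignable_fraction(aln), 0.5)
  fw <- forward_best_hit(c(q = full), J, param_setting(0.8, 1e3), sch, model)
  expect_null(fw)
  # the same hits pass at a permissive divergence
  fw <- forward_best_hit(c(q = full), J, param_setting(0.2, 1e3), sch, model)
  expect_identical(fw$j_id, "frag1")
})

test_that("reciprocal test confirms symmetric pairs and demands the cache", {
  sch <- fix_scheme()
  model <- fix_jtt()
  sim <- simulate_genome_pair(sim_config(n_genes = 10, t = 0.2, seed = 121),
                              model)
  setting <- param_setting(0.5, 1e-5)
  q <- sim$A$seqs[3]
  fw <- forward_best_hit(q, sim$B, setting, sch, model)
  pair <- reciprocal_confirm(q, sim$B$seqs[fw$j_id], sim$A, setting, sch,
                             model,
                             forward_cache = setNames(fw$distance, names(q)))
  expect_s3_class(pair, "ortholog_pair")
  expect_identical(pair$query_id, names(q))
  expect_equal(pair$distance, fw$distance)
  expect_error(
    reciprocal_confirm(q, sim$B$seqs[fw$j_id], sim$A, setting, sch, model,
                       forward_cache = c(other = 0.1)),
    "consistency")
})

test_that("a relative of j closer than i defeats the reciprocal test", {
  sch <- fix_scheme()
  model <- fix_jtt()
  set.seed(131)
  sim <- simulate_genome_pair(
    sim_config(n_genes = 6, length_range = c(200L, 200L), t = 0.6,
               seed = 131), model)
  setting <- param_setting(0.2, 1e-3)
  i_id <- sim$A$ids[1]
  j_id <- sim$truth$id_b[sim$truth$id_a == i_id]
  # plant in A a gene evolved only slightly away from j itself: it sits
  # closer to j than the true ortholog i does
  near_j <- evolve_sequence(sim$B$seqs[[j_id]], model, 0.05)
  A2 <- format_genome(c(sim$A$seqs, iprime = near_j), "Aplus.aa")
  tab <- rsd_orthologs(A2, sim$B, setting, sch, model)
  claimed <- tab$subject_id[tab$query_id == i_id]
  expect_false(j_id %in% claimed)        # reciprocal test rejected (i, j)
  expect_true("iprime" %in% tab$query_id) # the interloper pairs with j
  expect_identical(tab$subject_id[tab$query_id == "iprime"], j_id)
})

test_that("RSD pairs every sequence of a genome with its exact copy", {
  sch <- fix_scheme()
  model <- fix_jtt()
  sim <- simulate_genome_pair(sim_config(n_genes = 8, t = 0.2, seed = 141),
                              model)
  copy <- format_genome(setNames(unname(sim$A$seqs),
                                 paste0(sim$A$ids, "_c")), "Acopy.aa")
  tab <- rsd_orthologs(sim$A, copy, param_setting(0.8, 1e-10), sch, model)
  expect_identical(nrow(tab), 8L)
  expect_identical(tab$subject_id, paste0(tab$query_id, "_c"))
  expect_true(all(tab$distance <= 1e-6))
})

test_that("confirmation agrees with a cache-free brute-force reimplementation", {
  sch <- fix_scheme()
  model <- fix_jtt()
  sim <- simulate_genome_pair(
    sim_config(n_genes = 20, t = 0.4, paralog_fraction = 0.2, t_dup = 0.1,
               seed = 151), model)
  setting <- param_setting(0.5, 1e-5)
  tab <- rsd_orthologs(sim$A, sim$B, setting, sch, model)

  brute_distance <- function(x, y) {
    aln <- global_align(x, y, sch)
    if (alignable_fraction(aln) < setting$divergence) return(NA_real_)
    ml_distance(aln, model)$t_hat
  }
  brute <- list()
  for (qid in sim$A$ids) {
    q <- sim$A$seqs[qid]
    hs <- local_search(q, sim$B, sch, setting$evalue)
    d <- c()
    for (sid in hs$hits$subject_id) {
      dd <- brute_distance(q, sim$B$seqs[sid])
      if (!is.na(dd)) d[sid] <- dd
    }
    if (length(d) == 0L) next
    j <- names(d)[order(d, names(d))][1]
    hs2 <- local_search(sim$B$seqs[j], sim$A, sch, setting$evalue)
    d2 <- c()
    for (sid in hs2$hits$subject_id) {
      dd <- brute_distance(sim$B$seqs[j], sim$A$seqs[sid])
      if (!is.na(dd)) d2[sid] <- dd
    }
    if (qid %in% names(d2) && d2[qid] <= min(d2)) {
      brute[[length(brute) + 1L]] <- data.frame(
        query_id = qid, subject_id = j, distance = unname(d[j]),
        stringsAsFactors = FALSE)
    }
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$query_id), ]
  expect_identical(tab$query_id, brute$query_id)
  expect_identical(tab$subject_id, brute$subject_id)
  expect_equal(tab$distance, brute$distance, tolerance = 1e-12)
})

test_that("stored and on-the-fly hit sets give identical ortholog tables", {
  sch <- fix_scheme()
  model <- fix_jtt()
  sim <- simulate_genome_pair(sim_config(n_genes = 12, t = 0.3, seed = 161),
                              model)
  setting <- param_setting(0.5, 1e-5)
  direct <- rsd_orthologs(sim$A, sim$B, setting, sch, model)

  store <- result_store(withr::local_tempdir())
  put_dir <- function(qg, sg) {
    hit_sets <- lapply(qg$ids, function(id)
      local_search(qg$seqs[id], sg, sch, 1e-3, max_hits = Inf))
    store_put(store, "blast_result", sprintf("%s__%s.tsv", qg$name, sg$name),
              format_hit_table(hit_sets))
  }
  put_dir(sim$A, sim$B); put_dir(sim$B, sim$A)
  stored <- rsd_orthologs(sim$A, sim$B, setting, sch, model, store = store)
  expect_identical(format_ortholog_table(direct),
                   format_ortholog_table(stored))

  # a missing table is reported by name
  empty <- result_store(withr::local_tempdir())
  expect_error(rsd_orthologs(sim$A, sim$B, setting, sch, model,
                             store = empty),
               "simA.aa__simB.aa|simB.aa__simA.aa")
})

test_that("tightening either parameter never adds an ortholog pair", {
  sch <- fix_scheme()
  model <- fix_jtt()
  sim <- simulate_genome_pair(
    sim_config(n_genes = 10, t = 0.5, paralog_fraction = 0.2, t_dup = 0.1,
               seed = 171), model)
  keys <- function(tab) paste(tab$query_id, tab$subject_id)
  grid <- list(loose = param_setting(0.2, 1e-3),
               tight_e = param_setting(0.2, 1e-10),
               tight_d = param_setting(0.8, 1e-3),
               tight_both = param_setting(0.8, 1e-10))
  tabs <- lapply(grid, function(s)
    rsd_orthologs(sim$A, sim$B, s, sch, model, max_hits = Inf))
  expect_true(all(keys(tabs$tight_e) %in% keys(tabs$loose)))
  expect_true(all(keys(tabs$tight_d) %in% keys(tabs$loose)))
  expect_true(all(keys(tabs$tight_both) %in% keys(tabs$tight_e)))
  expect_true(all(keys(tabs$tight_both) %in% keys(tabs$tight_d)))
})

test_that("ortholog tables round-trip through their text serialization", {
  tab <- data.frame(query_id = c("a", "b"), subject_id = c("x", "y"),
                    distance = c(0.123456789012345, 1.5e-7),
                    stringsAsFactors = FALSE)
  back <- parse_ortholog_table(format_ortholog_table(tab))
  expect_identical(back$query_id, tab$query_id)
  expect_identical(back$distance, tab$distance)
  empty <- parse_ortholog_table(format_ortholog_table(tab[0, ]))
  expect_identical(nrow(empty), 0L)
})
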