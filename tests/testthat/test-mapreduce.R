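# Scripted task runners let the executor contract be exercised without
# real alignment work.
ok_runner <- function(...) {
  function(line, task_index, worker, attempt) list(lines = paste("done", line))
}

test_that("runner files enumerate exactly the required tasks", {
  s12 <- param_grid()  # 12 settings
  out <- withr::local_tempfile()

  # production-scale accounting: 55 new vs 399 existing genomes
  newn <- sprintf("N%03d.aa", 1:55)
  oldn <- sprintf("O%03d.aa", 1:399)
  ro <- generate_runner_file(newn, oldn, "ortholog", s12, out)
  expect_length(ro$lines, 281160L)
  rb <- generate_runner_file(newn, oldn, "blast", s12, out)
  expect_length(rb$lines, 46860L)

  # empty input, vacuous file
  r0 <- generate_runner_file(character(0), character(0), "blast", s12, out)
  expect_length(r0$lines, 0L)

  # small case: every line parses under the grammar, deterministic order
  r <- generate_runner_file(c("B.aa", "A.aa"), c("Z.aa"), "ortholog",
                            param_grid(0.8, c(1e-10, 1e-5)), out)
  expect_length(r$lines, (1 + 2) * 2)
  cmds <- lapply(r$lines, parse_command)
  expect_true(all(vapply(cmds, `[[`, character(1), "program") == "rsd-ortho"))
  expect_identical(cmds[[1]]$args[["--genome-a"]], "A.aa")
  expect_identical(cmds[[1]]$args[["--genome-b"]], "B.aa")

  # blast lines carry the most relaxed E-value of the settings
  rb2 <- generate_runner_file(c("A.aa", "B.aa"), character(0), "blast",
                              param_grid(0.8, c(1e-10, 1e-5)), out)
  expect_length(rb2$lines, 2L)
  expect_identical(parse_command(rb2$lines[1])$args[["--evalue"]], "1e-05")

  expect_error(generate_runner_file(c("A.aa"), c("A.aa"), "blast", s12, out),
               "both new and existing")
  expect_error(parse_command("rsd-frobnicate --x 1"), "unknown program")
  expect_error(parse_command("rsd-blast --query-genome A"), "flags")
})

test_that("successful tasks each leave one part file and a report", {
  store <- result_store(withr::local_tempdir())
  cfg <- executor_config(n_workers = 2)
  outdir <- file.path(store$root, "output")
  rep <- run_mapper(sprintf("task %d", 1:5), cfg, store, ok_runner(),
                    output_dir = outdir)
  expect_identical(rep$status, rep("ok", 5))
  expect_identical(sort(rep$task_index), 1:5)
  parts <- list.files(outdir, pattern = "^part-")
  expect_identical(sort(parts), sprintf("part-%05d", 0:4))
  expect_identical(sum(rep$status == "ok"), length(parts))
  expect_identical(readLines(file.path(outdir, "part-00000")), "done task 1")
})

test_that("an always-failing task is retried to the attempt cap", {
  store <- result_store(withr::local_tempdir())
  cfg <- executor_config(n_workers = 2, max_attempts = 4,
                         blacklist_threshold = 10)
  bad <- function(line, task_index, worker, attempt) stop("boom")
  rep <- run_mapper("only task", cfg, store, bad)
  expect_identical(rep$status, "failed")
  expect_identical(rep$attempts, 4L)
  expect_true(is.na(rep$part_file))
})

test_that("a worker failing repeatedly is blacklisted; the run completes", {
  store <- result_store(withr::local_tempdir())
  cfg <- executor_config(n_workers = 2, max_attempts = 4,
                         blacklist_threshold = 4)
  flaky <- function(line, task_index, worker, attempt) {
    if (worker == 1L) stop("worker 1 is broken")
    list(lines = paste("ok", line))
  }
  rep <- run_mapper(sprintf("t%d", 1:12), cfg, store, flaky)
  expect_identical(rep$status, rep("ok", 12))
  expect_true(all(rep$worker_id == 2L))
  log <- store_get(store, "log", "events.log")
  expect_true(any(grepl("blacklist", log)))
  # after the blacklist event, worker 1 never starts another attempt
  bl_at <- which(grepl("\t1\t.*blacklist", log))[1]
  later <- log[seq(bl_at + 1L, length(log))]
  expect_false(any(grepl("\t1\t\\d+\tstart", later)))
})

test_that("the run aborts when every worker is blacklisted", {
  store <- result_store(withr::local_tempdir())
  cfg <- executor_config(n_workers = 2, max_attempts = 4,
                         blacklist_threshold = 2)
  bad <- function(line, task_index, worker, attempt) stop("all broken")
  expect_error(run_mapper(sprintf("t%d", 1:6), cfg, store, bad),
               class = "rsdlite_all_blacklisted")
})

test_that("a task exceeding the timeout is recorded as timeout", {
  store <- result_store(withr::local_tempdir())
  cfg <- executor_config(n_workers = 1, task_timeout = 0.2, max_attempts = 2,
                         blacklist_threshold = 10)
  slow <- function(line, task_index, worker, attempt) {
    # busy work: the cooperative timeout interrupts R evaluation
    x <- 0
    for (i in 1:1e9) x <- x + i
    list(lines = "never reached")
  }
  t0 <- proc.time()[["elapsed"]]
  rep <- run_mapper("slow task", cfg, store, slow)
  expect_lt(proc.time()[["elapsed"]] - t0, 4)  # interrupted, not slept out
  expect_identical(rep$status, "timeout")
  expect_identical(rep$attempts, 2L)
})

test_that("the result store round-trips content and lists by prefix", {
  store <- result_store(withr::local_tempdir())
  lines <- c("query_id\tsubject_id", sprintf("q%d\ts%d", 1:50, 1:50))
  store_put(store, "blast_result", "A.aa__B.aa.tsv", lines)
  expect_identical(store_get(store, "blast_result", "A.aa__B.aa.tsv"), lines)
  store_put(store, "blast_result", "A.aa__C.aa.tsv", "x")
  store_put(store, "ortholog_results", "A.aa__B.aa__d0.8_e1e-10.orth", "y")
  expect_identical(store_list(store, "blast_result", prefix = "A.aa__"),
                   c("A.aa__B.aa.tsv", "A.aa__C.aa.tsv"))
  expect_error(store_get(store, "blast_result", "missing.tsv"), "missing")
  expect_error(store_put(store, "nope", "k", "v"), "unknown bucket")
})

test_that("hit tables round-trip through their text serialization", {
  hs <- list(structure(list(query_id = "q1", subject_genome = "B.aa",
                            hits = data.frame(subject_id = c("s1", "s2"),
                                              raw_score = c(120L, 40L),
                                              evalue = c(1.25e-30, 3e-4))),
                       class = "hit_set"),
             structure(list(query_id = "q2", subject_genome = "B.aa",
                            hits = data.frame(subject_id = character(0),
                                              raw_score = integer(0),
                                              evalue = numeric(0))),
                       class = "hit_set"))
  back <- parse_hit_table(format_hit_table(hs))
  expect_identical(back$query_id, c("q1", "q1"))
  expect_identical(back$raw_score, c(120L, 40L))
  expect_identical(back$evalue, c(1.25e-30, 3e-4))
})

test_that("two-phase workflow is complete, resumable, and idempotent", {
  sch <- fix_scheme()
  model <- fix_jtt()
  genomes <- lapply(1:3, function(i) {
    sim <- simulate_genome_pair(sim_config(n_genes = 6, t = 0.2,
                                           seed = 200 + i), model)
    format_genome(sim$A$seqs, sprintf("G%d.aa", i))
  })
  settings <- param_grid(0.5, c(1e-10, 1e-5))
  cfg <- executor_config(n_workers = 2)
  store <- result_store(withr::local_tempdir())

  res <- run_two_phase(genomes, list(), settings, cfg, store, sch, model)
  expect_identical(res$summary$blast$tasks, 6L)     # 3 pairs x 2 directions
  expect_identical(res$summary$ortholog$tasks, 6L)  # 3 pairs x 2 settings
  expect_identical(res$summary$blast$ok, 6L)
  expect_identical(res$summary$ortholog$ok, 6L)
  expect_length(store_list(store, "blast_result"), 6L)
  expect_length(store_list(store, "ortholog_results"), 6L)

  # phase 2 alone (fresh invocation over the same store) is idempotent
  before <- lapply(store_list(store, "ortholog_results"), function(k)
    store_get(store, "ortholog_results", k))
  res2 <- run_ortholog_phase(genomes, list(), settings, cfg, store, sch,
                             model)
  expect_identical(res2$summary$ok, 6L)
  after <- lapply(store_list(store, "ortholog_results"), function(k)
    store_get(store, "ortholog_results", k))
  expect_identical(before, after)

  # deleting a blast table makes phase 2 refuse, naming the entry
  gone <- store_list(store, "blast_result")[1]
  unlink(file.path(store$root, "blast_result", gone))
  expect_error(run_ortholog_phase(genomes, list(), settings, cfg, store,
                                  sch, model),
               gone, fixed = TRUE)
})
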