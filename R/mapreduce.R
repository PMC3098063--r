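#' Executor configuration
#'
#' Mirrors the knobs a streaming map framework exposes, reinterpreted for
#' a local pool of logical workers: pool size, a per-task timeout (the
#' production "goldilocks" value is 86400 s, ~24 h, chosen to separate
#' long-running from hung jobs), a retry cap, consecutive-failure
#' blacklisting of workers, and (off by default, as wide task-duration
#' variance makes it wasteful) speculative re-execution of slow tasks.
#'
#' @param n_workers Number of logical workers (>= 1).
#' @param task_timeout Seconds before a running task is killed and counted
#'   as a timeout.
#' @param max_attempts Maximum attempts per task (default 4).
#' @param blacklist_threshold Consecutive failures after which a worker is
#'   removed from the pool (default 4).
#' @param speculative If `TRUE`, a task attempt that took longer than twice
#'   the median elapsed time of completed tasks is re-run once on another
#'   worker and the faster result wins.
#' @return A list of class `executor_config`.
#' @export
executor_config <- function(n_workers = 2L, task_timeout = 86400,
                            max_attempts = 4L, blacklist_threshold = 4L,
                            speculative = FALSE) {
  stopifnot(n_workers >= 1L, task_timeout > 0, max_attempts >= 1L,
            blacklist_threshold >= 1L)
  structure(list(n_workers = as.integer(n_workers),
                 task_timeout = task_timeout,
                 max_attempts = as.integer(max_attempts),
                 blacklist_threshold = as.integer(blacklist_threshold),
                 speculative = isTRUE(speculative)),
            class = "executor_config")
}

# ---- runner-file command grammar ----
# rsd-blast --query-genome A --db-genome B --evalue E
# rsd-ortho --genome-a A --genome-b B --divergence D --evalue E
# Whitespace-separated, no shell interpretation.

#' Parse one runner-file command line
#' @param line A command line in the runner-file grammar.
#' @return List with `program` and named `args`.
#' @export
parse_command <- function(line) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(toks) == 0L) stop("empty command line")
  prog <- toks[1L]
  spec <- list(
    "rsd-blast" = c("--query-genome", "--db-genome", "--evalue"),
    "rsd-ortho" = c("--genome-a", "--genome-b", "--divergence", "--evalue"))
  if (!prog %in% names(spec)) {
    stop("unknown program '", prog, "' in runner line: ", line)
  }
  rest <- toks[-1L]
  if (length(rest) %% 2L != 0L) stop("malformed runner line: ", line)
  flags <- rest[seq(1L, length(rest), by = 2L)]
  vals <- rest[seq(2L, length(rest), by = 2L)]
  if (!setequal(flags, spec[[prog]]) || anyDuplicated(flags)) {
    stop("runner line for ", prog, " must have exactly the flags ",
         paste(spec[[prog]], collapse = " "), ": ", line)
  }
  list(program = prog, args = setNames(vals, flags))
}

#' Generate a runner file
#'
#' Writes the plain-text file of command lines, one map task per line, that
#' drives a phase of the workflow.  For phase `"blast"` there is one line
#' per ordered direction of every compared pair of genomes (new-vs-new and
#' new-vs-existing, both directions); the search threshold on those lines
#' is the most relaxed E-value in `settings`, so the stored tables serve
#' every setting.  For phase `"ortholog"` there is one line per unordered
#' compared pair per setting.  Line order is deterministic: genome names
#' sorted, new-new pairs before new-existing, settings in grid order.
#'
#' @param genome_names Names of the new genomes (N).
#' @param existing_names Names of previously processed genomes (O).
#' @param phase `"blast"` or `"ortholog"`.
#' @param settings List of `param_setting`.
#' @param out Output file path.
#' @return An object of class `runner_file`: `path`, `phase`, `lines`.
#' @export
generate_runner_file <- function(genome_names, existing_names = character(0),
                                 phase = c("blast", "ortholog"), settings,
                                 out) {
  phase <- match.arg(phase)
  stopifnot(!anyDuplicated(genome_names), !anyDuplicated(existing_names))
  overlap <- intersect(genome_names, existing_names)
  if (length(overlap) > 0L) {
    stop("genomes listed as both new and existing: ",
         paste(overlap, collapse = ", "))
  }
  new <- sort(genome_names)
  old <- sort(existing_names)
  pa <- pb <- character(0)
  if (length(new) >= 2L) {
    idx <- which(upper.tri(matrix(0, length(new), length(new))), arr.ind = TRUE)
    idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
    pa <- new[idx[, "row"]]
    pb <- new[idx[, "col"]]
  }
  if (length(new) >= 1L && length(old) >= 1L) {
    pa <- c(pa, rep(new, each = length(old)))
    pb <- c(pb, rep(old, times = length(new)))
  }
  if (phase == "blast") {
    e_relaxed <- formatC(max(vapply(settings, `[[`, numeric(1), "evalue")),
                         format = "g")
    fwd <- sprintf("rsd-blast --query-genome %s --db-genome %s --evalue %s",
                   pa, pb, e_relaxed)
    rev <- sprintf("rsd-blast --query-genome %s --db-genome %s --evalue %s",
                   pb, pa, e_relaxed)
    lines <- as.vector(rbind(fwd, rev))  # both directions, pair-major
  } else {
    ds <- vapply(settings, function(s) formatC(s$divergence, format = "g"),
                 character(1))
    es <- vapply(settings, function(s) formatC(s$evalue, format = "g"),
                 character(1))
    k <- length(settings)
    lines <- sprintf("rsd-ortho --genome-a %s --genome-b %s --divergence %s --evalue %s",
                     rep(pa, each = k), rep(pb, each = k),
                     rep(ds, times = length(pa)), rep(es, times = length(pa)))
  }
  writeLines(lines, out)
  structure(list(path = out, phase = phase, lines = lines),
            class = "runner_file")
}

#' Task runner for the RSD command grammar
#'
#' Builds the function the executor applies to each runner line.
#' `rsd-blast` lines search every query of the query genome against the
#' subject genome (untruncated hit lists) and store the table under
#' `blast_result/`; `rsd-ortho` lines run the RSD decision procedure
#' reading only stored hit tables and store the ortholog table under
#' `ortholog_results/`.
#'
#' @param genomes Named list of `genome_db` objects (names = genome names).
#' @param scheme A `scoring_scheme`.
#' @param model A `rate_model`.
#' @param store A `result_store`.
#' @param max_hits Hit-list truncation used by the ortholog step.
#' @return A function `(line, task_index, worker, attempt)` returning
#'   `list(lines =, bucket =, key =)`.
#' @export
rsd_task_runner <- function(genomes, scheme, model, store, max_hits = 20L) {
  get_genome <- function(name) {
    g <- genomes[[name]]
    if (is.null(g)) stop("unknown genome '", name, "' in runner line")
    g
  }
  function(line, task_index, worker, attempt) {
    cmd <- parse_command(line)
    if (cmd$program == "rsd-blast") {
      qg <- get_genome(cmd$args[["--query-genome"]])
      sg <- get_genome(cmd$args[["--db-genome"]])
      ev <- as.numeric(cmd$args[["--evalue"]])
      hit_sets <- lapply(qg$ids, function(id) {
        local_search(list(id = id, seq = qg$seqs[[id]]), sg, scheme,
                     evalue_threshold = ev, max_hits = Inf)
      })
      list(lines = format_hit_table(hit_sets), bucket = "blast_result",
           key = hit_table_key(qg$name, sg$name))
    } else {
      ga <- get_genome(cmd$args[["--genome-a"]])
      gb <- get_genome(cmd$args[["--genome-b"]])
      setting <- param_setting(as.numeric(cmd$args[["--divergence"]]),
                               as.numeric(cmd$args[["--evalue"]]))
      tab <- rsd_orthologs(ga, gb, setting, scheme, model, store = store,
                           max_hits = max_hits)
      list(lines = format_ortholog_table(tab), bucket = "ortholog_results",
           key = ortholog_key(ga$name, gb$name, setting))
    }
  }
}

#' Run a mapper over a runner file
#'
#' Dispatches each runner line, in order, to a pool of logical workers.
#' Every successful task writes one part file (`part-00000`-style, keyed to
#' the task index) under `output_dir` and, when the task declares a
#' bucket/key, copies its payload into the store.  A task attempt whose
#' elapsed time exceeds `config$task_timeout` is interrupted and recorded
#' as `"timeout"` (the timeout is cooperative: it interrupts R evaluation,
#' not blocking foreign calls); failed and timed-out attempts are retried
#' (preferring a
#' different worker) up to `config$max_attempts`.  A worker accumulating
#' `config$blacklist_threshold` consecutive failures is blacklisted and
#' receives no further work; if every worker is blacklisted while tasks
#' remain, the run aborts with an error carrying the partial reports.
#' There is no reducer stage: the part files are the final output.
#'
#' @param runner A `runner_file` (or a character vector of lines).
#' @param config An `executor_config`.
#' @param store A `result_store` (event log + payload buckets).
#' @param task_runner Function `(line, task_index, worker, attempt)`
#'   returning `list(lines =, bucket =, key =)` (`bucket`/`key` may be
#'   omitted to write only the part file).  Defaults must be supplied via
#'   [rsd_task_runner()] for RSD command lines.
#' @param output_dir Directory for part files (default `<store>/output`).
#' @return Data frame of task reports: `task_index`, `status`
#'   (`"ok"`/`"failed"`/`"timeout"`), `attempts`, `worker_id`, `elapsed`,
#'   `part_file` (`NA` unless ok).
#' @export
run_mapper <- function(runner, config, store, task_runner,
                       output_dir = file.path(store$root, "output")) {
  lines <- if (inherits(runner, "runner_file")) runner$lines else runner
  stopifnot(inherits(config, "executor_config"), is.function(task_runner))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(lines)
  consec_fail <- integer(config$n_workers)
  blacklisted <- logical(config$n_workers)
  rr <- 0L  # round-robin pointer
  next_worker <- function(exclude = 0L) {
    active <- which(!blacklisted)
    if (length(active) == 0L) return(NA_integer_)
    if (length(active) > 1L) active <- setdiff(active, exclude)
    rr <<- rr + 1L
    active[(rr - 1L) %% length(active) + 1L]
  }
  elapsed_done <- numeric(0)
  attempt_once <- function(line, idx, worker, attempt) {
    store_log(store, worker, idx, sprintf("start attempt=%d", attempt))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      setTimeLimit(elapsed = config$task_timeout, transient = TRUE)
      on.exit(setTimeLimit(elapsed = Inf, transient = TRUE), add = TRUE)
      payload <- task_runner(line, idx, worker, attempt)
      list(ok = TRUE, payload = payload)
    }, error = function(e) {
      list(ok = FALSE, message = conditionMessage(e))
    })
    el <- proc.time()[["elapsed"]] - t0
    timed_out <- !res$ok &&
      (el >= config$task_timeout ||
         grepl("time limit|elapsed time", res$message, ignore.case = TRUE))
    list(ok = res$ok, payload = res$payload, elapsed = el,
         timeout = timed_out,
         message = if (res$ok) NULL else res$message)
  }
  reports <- vector("list", n)
  for (idx in seq_len(n)) {
    line <- lines[idx]
    status <- "failed"; attempts <- 0L; worker_used <- NA_integer_
    elapsed <- 0; part <- NA_character_
    last_worker <- 0L
    while (attempts < config$max_attempts) {
      worker <- next_worker(exclude = last_worker)
      if (is.na(worker)) {
        rep_df <- do.call(rbind, reports[!vapply(reports, is.null, logical(1))])
        cond <- structure(
          class = c("rsdlite_all_blacklisted", "error", "condition"),
          list(message = sprintf(
                 "all %d workers blacklisted with %d task(s) pending",
                 config$n_workers, n - idx + 1L),
               call = sys.call(-1), reports = rep_df))
        stop(cond)
      }
      attempts <- attempts + 1L
      last_worker <- worker
      a <- attempt_once(line, idx, worker, attempts)
      elapsed <- a$elapsed
      worker_used <- worker
      if (a$ok) {
        status <- "ok"
        consec_fail[worker] <- 0L
        # speculative re-run of a conspicuously slow attempt
        if (config$speculative && length(elapsed_done) >= 3L &&
            elapsed > 2 * median(elapsed_done)) {
          w2 <- next_worker(exclude = worker)
          if (!is.na(w2) && w2 != worker) {
            store_log(store, w2, idx, "speculate")
            b <- attempt_once(line, idx, w2, attempts)
            if (b$ok && b$elapsed < elapsed) {
              a <- b; elapsed <- b$elapsed; worker_used <- w2
            }
          }
        }
        elapsed_done <- c(elapsed_done, elapsed)
        part <- file.path(output_dir, sprintf("part-%05d", idx - 1L))
        payload <- a$payload
        writeLines(if (is.null(payload$lines)) character(0) else payload$lines,
                   part)
        if (!is.null(payload$bucket) && !is.null(payload$key)) {
          store_put(store, payload$bucket, payload$key, payload$lines)
        }
        store_log(store, worker_used, idx, "ok")
        break
      }
      status <- if (a$timeout) "timeout" else "failed"
      consec_fail[worker] <- consec_fail[worker] + 1L
      store_log(store, worker, idx, status)
      if (consec_fail[worker] >= config$blacklist_threshold) {
        blacklisted[worker] <- TRUE
        store_log(store, worker, idx, "blacklist")
      }
      if (attempts < config$max_attempts) {
        store_log(store, worker, idx, "retry")
      }
    }
    reports[[idx]] <- data.frame(
      task_index = idx, status = status, attempts = attempts,
      worker_id = worker_used, elapsed = elapsed,
      part_file = if (status == "ok") part else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}

phase_summary <- function(reports) {
  list(tasks = nrow(reports),
       ok = sum(reports$status == "ok"),
       failed = sum(reports$status == "failed"),
       timeout = sum(reports$status == "timeout"))
}

#' Run the search (BLAST-equivalent) phase
#'
#' Generates the blast runner file for the given genomes and executes it,
#' filling the store's `blast_result/` bucket with one untruncated hit
#' table per ordered genome pair.
#'
#' @param new,existing Lists of `genome_db` objects (existing genomes are
#'   only compared against new ones, never among themselves).
#' @param settings List of `param_setting` (the search threshold is the
#'   most relaxed E-value among them).
#' @param config An `executor_config`.
#' @param store A `result_store`.
#' @param scheme,model Scoring scheme and rate model.
#' @return List with the runner file, task reports and a count summary.
#' @export
run_blast_phase <- function(new, existing = list(), settings, config, store,
                            scheme, model) {
  genomes <- c(new, existing)
  names(genomes) <- vapply(genomes, `[[`, character(1), "name")
  runner <- generate_runner_file(
    vapply(new, `[[`, character(1), "name"),
    vapply(existing, `[[`, character(1), "name"),
    phase = "blast", settings = settings,
    out = file.path(store$root, "blast_runner"))
  reports <- run_mapper(runner, config, store,
                        rsd_task_runner(genomes, scheme, model, store),
                        output_dir = file.path(store$root, "output", "blast"))
  list(runner = runner, reports = reports, summary = phase_summary(reports))
}

#' Run the ortholog-estimation phase
#'
#' Verifies that the store holds every hit table the phase needs (aborting
#' with the list of missing entries otherwise), generates the ortholog
#' runner file, and executes it.  Reads only the store, so it can run in a
#' separate process invocation from the search phase, any time later.
#'
#' @inheritParams run_blast_phase
#' @param max_hits Hit-list truncation used by the ortholog step.
#' @return List with the runner file, task reports and a count summary.
#' @export
run_ortholog_phase <- function(new, existing = list(), settings, config,
                               store, scheme, model, max_hits = 20L) {
  genomes <- c(new, existing)
  names(genomes) <- vapply(genomes, `[[`, character(1), "name")
  new_names <- sort(vapply(new, `[[`, character(1), "name"))
  old_names <- sort(vapply(existing, `[[`, character(1), "name"))
  required <- character(0)
  add_pair <- function(a, b) c(hit_table_key(a, b), hit_table_key(b, a))
  if (length(new_names) >= 2L) {
    for (i in seq_len(length(new_names) - 1L)) {
      for (j in (i + 1L):length(new_names)) {
        required <- c(required, add_pair(new_names[i], new_names[j]))
      }
    }
  }
  for (a in new_names) for (b in old_names) {
    required <- c(required, add_pair(a, b))
  }
  missing <- required[!vapply(required, store_exists, logical(1),
                              store = store, bucket = "blast_result")]
  if (length(missing) > 0L) {
    stop("cannot start the ortholog phase; store is missing hit tables: ",
         paste(missing, collapse = ", "))
  }
  runner <- generate_runner_file(new_names, old_names, phase = "ortholog",
                                 settings = settings,
                                 out = file.path(store$root, "ortho_runner"))
  reports <- run_mapper(runner, config, store,
                        rsd_task_runner(genomes, scheme, model, store),
                        output_dir = file.path(store$root, "output", "ortho"))
  list(runner = runner, reports = reports, summary = phase_summary(reports))
}

#' Run the complete two-phase workflow
#'
#' Phase 1 computes and stores all hit tables; phase 2 consumes only the
#' store and writes the ortholog tables.  Because the phases communicate
#' exclusively through the store, `(phase1; phase2)` and
#' `(phase1; process exit; phase2)` produce identical outputs, and phase 2
#' alone succeeds whenever the store is complete.
#'
#' @inheritParams run_ortholog_phase
#' @return List of class `two_phase_summary` with per-phase reports and
#'   counts.
#' @export
run_two_phase <- function(new, existing = list(), settings, config, store,
                          scheme, model, max_hits = 20L) {
  p1 <- run_blast_phase(new, existing, settings, config, store, scheme, model)
  p2 <- run_ortholog_phase(new, existing, settings, config, store, scheme,
                           model, max_hits = max_hits)
  structure(list(blast = p1, ortholog = p2,
                 summary = list(blast = p1$summary, ortholog = p2$summary)),
            class = "two_phase_summary")
}

#' @export
print.two_phase_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<two_phase_summary> blast: %d tasks (%d ok); ortholog: %d tasks (%d ok)\n",
              s$blast$tasks, s$blast$ok, s$ortholog$tasks, s$ortholog$ok))
  invisible(x)
}
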