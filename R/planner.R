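#' Number of genome pairs to compare
#'
#' All pairs among the N new genomes plus every new-vs-existing pair:
#' `N(N-1)/2 + N*O`.  Existing genomes are never re-compared among
#' themselves.
#'
#' @param N Number of new genomes awaiting computation (>= 0).
#' @param O Number of genomes previously processed (>= 0).
#' @return Integer pair count.
#' @export
pair_count <- function(N, O = 0) {
  stopifnot(N >= 0, O >= 0)
  as.numeric(N) * (N - 1) / 2 + as.numeric(N) * O
}

#' Plan input for the workload model
#'
#' @param N,O New / previously processed genome counts.
#' @param M Number of (divergence, E-value) parameter settings (>= 1); the
#'   classical production grid has 12.
#' @param hours_per_process Average wall hours per ortholog process
#'   (4 h is a lower bound for large genomes).
#' @param cores Cores available continuously.
#' @return A list of class `plan_input`.
#' @export
plan_input <- function(N, O = 0, M = 12, hours_per_process = 4, cores = 300) {
  stopifnot(N >= 0, O >= 0, M >= 1, hours_per_process > 0, cores >= 1)
  structure(list(N = N, O = O, M = M,
                 hours_per_process = hours_per_process, cores = cores),
            class = "plan_input")
}

#' Total ortholog processes for a plan
#'
#' `f(N, O, M) = (N*O + N(N-1)/2) * M`: one process per compared genome
#' pair per parameter setting.
#'
#' @param plan A `plan_input`.
#' @return Number of ortholog-estimation processes.
#' @export
process_count <- function(plan) {
  stopifnot(inherits(plan, "plan_input"))
  pair_count(plan$N, plan$O) * plan$M
}

#' Job counts for the two-phase workflow
#'
#' The search phase runs each compared pair in both directions (x2); the
#' ortholog phase runs each pair once per parameter setting (xM).
#'
#' @param plan A `plan_input`.
#' @return List with `blast`, `ortholog`, `total`.
#' @export
total_job_count <- function(plan) {
  stopifnot(inherits(plan, "plan_input"))
  pc <- pair_count(plan$N, plan$O)
  list(blast = 2 * pc, ortholog = pc * plan$M,
       total = 2 * pc + pc * plan$M)
}

#' Serial-to-parallel time projection
#'
#' @param processes Number of processes.
#' @param hours_per_process Average hours each takes.
#' @param cores Cores available continuously.
#' @return List with `hours` and `years` (years rounded to 1 decimal, the
#'   conventional reporting precision).
#' @export
time_projection <- function(processes, hours_per_process = 4, cores = 300) {
  stopifnot(cores >= 1)
  hours <- processes * hours_per_process / cores
  list(hours = hours, years = round(hours / 8760, 1))
}

#' Instance type specification
#'
#' @param name Instance type label.
#' @param cores Cores per instance.
#' @param count Number of instances.
#' @param hours Hours each instance runs.
#' @param rate_per_hour USD per instance-hour.
#' @return A list of class `instance_spec`.
#' @export
instance_spec <- function(name, cores, count, hours, rate_per_hour) {
  stopifnot(cores >= 1, count >= 1, hours > 0, rate_per_hour > 0)
  structure(list(name = name, cores = cores, count = count, hours = hours,
                 rate_per_hour = rate_per_hour),
            class = "instance_spec")
}

#' Total cost of an instance reservation
#'
#' `count * hours * rate`, rounded to whole dollars (the precision cost
#' comparisons are conventionally printed at).
#'
#' @param spec An `instance_spec`.
#' @return Cost in USD.
#' @export
instance_cost <- function(spec) {
  stopifnot(inherits(spec, "instance_spec"))
  round(spec$count * spec$hours * spec$rate_per_hour)
}

#' Hours needed per instance for a fixed amount of work
#'
#' Under the constant-work model (total core-hours fixed), the hours column
#' of a cost comparison follows from the fleet size and cores per instance.
#'
#' @param total_core_hours Total core-hours of work.
#' @param count Number of instances.
#' @param cores_per_instance Cores per instance.
#' @return Hours each instance must run.
#' @export
instance_hours <- function(total_core_hours, count, cores_per_instance) {
  stopifnot(total_core_hours > 0, count >= 1, cores_per_instance >= 1)
  total_core_hours / (count * cores_per_instance)
}

#' Bundled instance-type cost table
#'
#' Reads the packaged table of cloud instance types (name, cores, fleet
#' size, hours, hourly rate) used by [plan_summary()]'s cost comparison.
#'
#' @return Data frame with one row per instance type.
#' @export
instance_table <- function() {
  path <- system.file("extdata", "instance_types.tsv", package = "rsdlite")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Workload and cost summary for an all-against-all run
#'
#' Combines the pair count, both BLAST task-count conventions (the
#' bidirectional task count used by the runner generator, and the unordered
#' new-vs-existing cross-pair count some summaries print), ortholog and
#' total job counts, the serial time projection, and the per-instance-type
#' cost table.
#'
#' @param plan A `plan_input`.
#' @return A list of class `plan_summary`.
#' @export
plan_summary <- function(plan) {
  stopifnot(inherits(plan, "plan_input"))
  jobs <- total_job_count(plan)
  proj <- time_projection(process_count(plan), plan$hours_per_process,
                          plan$cores)
  costs <- instance_table()
  costs$cost <- vapply(seq_len(nrow(costs)), function(i) {
    instance_cost(instance_spec(costs$name[i], costs$cores[i],
                                costs$count[i], costs$hours[i],
                                costs$rate_per_hour[i]))
  }, numeric(1))
  structure(list(
    N = plan$N, O = plan$O, M = plan$M,
    total_genomes = plan$N + plan$O,
    pairs = pair_count(plan$N, plan$O),
    cross_pairs = as.numeric(plan$N) * plan$O,
    blast_tasks_bidirectional = jobs$blast,
    ortholog_tasks = jobs$ortholog,
    total_jobs = jobs$total,
    hours = proj$hours, years = proj$years,
    costs = costs), class = "plan_summary")
}

#' @export
print.plan_summary <- function(x, ...) {
  cat(sprintf("RSD workload plan: N = %d new, O = %d existing (%d genomes), M = %d settings\n",
              x$N, x$O, x$total_genomes, x$M))
  cat(sprintf("  genome pairs:                 %s\n", format(x$pairs, big.mark = ",")))
  cat(sprintf("  cross pairs (new x existing): %s\n", format(x$cross_pairs, big.mark = ",")))
  cat(sprintf("  blast tasks (bidirectional):  %s\n",
              format(x$blast_tasks_bidirectional, big.mark = ",")))
  cat(sprintf("  ortholog tasks:               %s\n", format(x$ortholog_tasks, big.mark = ",")))
  cat(sprintf("  total jobs:                   %s\n", format(x$total_jobs, big.mark = ",")))
  cat(sprintf("  projected serial time:        %s hours (%.1f years)\n",
              format(x$hours, big.mark = ","), x$years))
  cat("  instance cost comparison:\n")
  for (i in seq_len(nrow(x$costs))) {
    cat(sprintf("    %-28s %3d x %6.0f h @ $%.3f/h = $%s\n",
                x$costs$name[i], x$costs$count[i], x$costs$hours[i],
                x$costs$rate_per_hour[i],
                format(x$costs$cost[i], big.mark = ",")))
  }
  invisible(x)
}
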