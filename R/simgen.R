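#' Simulation configuration for a synthetic genome pair
#'
#' Defines a pair of genomes descended from a common ancestor: `n_genes`
#' ortholog families diverge for a total of `t` substitutions per site
#' (`t/2` on each branch); a fraction of families additionally spawn a
#' recent paralog in genome A (a duplicate of the genome-A copy, evolved a
#' further `t_dup`, so it sits about `t + t_dup` from the genome-B
#' ortholog); a fraction of extra genes are unrelated
#' singletons present in one genome only.  Site rates are drawn from the
#' model's discrete-gamma categories, so the simulator stays exactly
#' within the distance estimator's model (no indels in families; gene
#' lengths are uniform on `length_range`).
#'
#' @param n_genes Number of ortholog families.
#' @param length_range Integer `c(min, max)` gene length in residues.
#' @param t True ortholog divergence (substitutions/site, >= 0).
#' @param paralog_fraction Fraction of families with a paralog in A.
#' @param t_dup Extra divergence of the paralog branch.
#' @param unrelated_fraction Fraction (of `n_genes`) of extra unrelated
#'   genes added to each genome.
#' @param alpha Gamma shape for among-site rate variation.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100L, length_range = c(100L, 400L),
                       t = 0.3, paralog_fraction = 0, t_dup = 0.05,
                       unrelated_fraction = 0, alpha = 1, seed = 1L) {
  stopifnot(n_genes >= 0, length(length_range) == 2L,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            t >= 0, t_dup >= 0, alpha > 0,
            paralog_fraction >= 0, unrelated_fraction >= 0,
            paralog_fraction <= 1, unrelated_fraction <= 1,
            paralog_fraction + unrelated_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 length_range = as.integer(length_range), t = t,
                 paralog_fraction = paralog_fraction, t_dup = t_dup,
                 unrelated_fraction = unrelated_fraction, alpha = alpha,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Uniform integer draw on [lo, hi] that is safe when lo == hi (sample()
# would reinterpret a scalar as 1:x).
draw_length <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Evolve integer-encoded states for time t; rates is the per-site rate
# multiplier vector.  Sites are grouped by (rate category, ancestral state)
# so only a handful of multinomial draws are needed.
evolve_states <- function(states, rates, model, t) {
  if (t == 0) return(states)
  out <- states
  for (r in unique(rates)) {
    P <- transition_matrix(model, t, r)
    sel <- which(rates == r)
    for (s in unique(states[sel])) {
      idx <- sel[states[sel] == s]
      out[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[s, ])
    }
  }
  out
}

#' Evolve one amino-acid sequence under a rate model
#'
#' Utility for building custom fixtures: substitutes residues according to
#' `exp(Q t)` with fresh per-site gamma category rates.
#'
#' @param seq Amino-acid string (canonical residues only).
#' @param model A `rate_model`.
#' @param t Branch length in substitutions/site.
#' @return The evolved amino-acid string.
#' @export
evolve_sequence <- function(seq, model, t) {
  states <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], AA_ORDER)
  if (anyNA(states)) stop("sequence must contain only canonical residues")
  rates <- sample(model$category_rates, length(states), replace = TRUE)
  paste(AA_ORDER[evolve_states(states, rates, model, t)], collapse = "")
}

#' Simulate a genome pair with known homology structure
#'
#' Samples ancestral genes site-wise from the model's stationary
#' frequencies, evolves two descendant copies independently for `t/2`
#' each (genomes A and B), adds paralogs and unrelated singletons per the
#' configuration, and records every relation in a truth table.
#'
#' @param cfg A `sim_config`.
#' @param model A `rate_model` (its gamma categories are re-derived at
#'   `cfg$alpha` for the per-site rates).
#' @return List with `A` and `B` (`genome_db`, named `"simA.aa"` /
#'   `"simB.aa"`) and `truth`, a data frame with columns `id_a`, `id_b`,
#'   `relation` (`"ortholog"`, `"paralog"`, `"none"`), `true_t`.
#' @export
simulate_genome_pair <- function(cfg, model) {
  stopifnot(inherits(cfg, "sim_config"), inherits(model, "rate_model"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  rates_pool <- gamma_category_rates(cfg$alpha, model$K)
  seqs_a <- character(0); seqs_b <- character(0)
  truth <- list()
  pal <- function(states) paste(AA_ORDER[states], collapse = "")
  n_par <- round(cfg$paralog_fraction * cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    L <- draw_length(cfg$length_range[1], cfg$length_range[2])
    rates <- sample(rates_pool, L, replace = TRUE)
    anc <- sample.int(20L, L, replace = TRUE, prob = model$pi)
    ida <- sprintf("gA%04d", g); idb <- sprintf("gB%04d", g)
    da <- evolve_states(anc, rates, model, cfg$t / 2)
    seqs_a[ida] <- pal(da)
    seqs_b[idb] <- pal(evolve_states(anc, rates, model, cfg$t / 2))
    truth[[length(truth) + 1L]] <- data.frame(
      id_a = ida, id_b = idb, relation = "ortholog", true_t = cfg$t,
      stringsAsFactors = FALSE)
    if (g <= n_par) {
      # recent duplication within lineage A: copy the A descendant and let
      # the copy diverge a further t_dup; require at least one substitution
      # so the paralog is distinguishable from its template
      idp <- sprintf("gA%04dp", g)
      dp <- evolve_states(da, rates, model, cfg$t_dup)
      if (cfg$t_dup > 0) {
        tries <- 0L
        while (all(dp == da) && tries < 20L) {
          dp <- evolve_states(da, rates, model, cfg$t_dup)
          tries <- tries + 1L
        }
      }
      seqs_a[idp] <- pal(dp)
      truth[[length(truth) + 1L]] <- data.frame(
        id_a = idp, id_b = idb, relation = "paralog",
        true_t = cfg$t + cfg$t_dup, stringsAsFactors = FALSE)
    }
  }
  n_unrel <- round(cfg$unrelated_fraction * cfg$n_genes)
  for (u in seq_len(n_unrel)) {
    L <- draw_length(cfg$length_range[1], cfg$length_range[2])
    idu <- sprintf("uA%04d", u)
    seqs_a[idu] <- pal(sample.int(20L, L, replace = TRUE, prob = model$pi))
    truth[[length(truth) + 1L]] <- data.frame(
      id_a = idu, id_b = NA_character_, relation = "none", true_t = NA_real_,
      stringsAsFactors = FALSE)
    L <- draw_length(cfg$length_range[1], cfg$length_range[2])
    idu <- sprintf("uB%04d", u)
    seqs_b[idu] <- pal(sample.int(20L, L, replace = TRUE, prob = model$pi))
    truth[[length(truth) + 1L]] <- data.frame(
      id_a = NA_character_, id_b = idu, relation = "none", true_t = NA_real_,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id_a = character(0), id_b = character(0),
               relation = character(0), true_t = numeric(0),
               stringsAsFactors = FALSE)
  if (cfg$n_genes == 0L && n_unrel == 0L) {
    return(list(A = NULL, B = NULL, truth = truth))
  }
  list(A = format_genome(seqs_a, "simA.aa"),
       B = format_genome(seqs_b, "simB.aa"),
       truth = truth)
}

#' Score predicted ortholog pairs against simulation truth
#'
#' Sensitivity is the fraction of true ortholog pairs recovered; precision
#' is the fraction of predicted pairs that are true orthologs (predictions
#' matching a paralog row, or matching nothing, count against it).  With no
#' predictions, precision is undefined and returned as `NA` with
#' `flagged = TRUE`.
#'
#' @param pairs An `ortholog_table` (or data frame with `query_id`,
#'   `subject_id`), query ids from genome A.
#' @param truth Truth table from [simulate_genome_pair()].
#' @return List with `sensitivity`, `precision`, `n_true`, `n_predicted`,
#'   `n_correct`, `flagged`.
#' @export
score_against_truth <- function(pairs, truth) {
  orth <- truth[truth$relation == "ortholog", , drop = FALSE]
  true_keys <- paste(orth$id_a, orth$id_b)
  pred_keys <- paste(pairs$query_id, pairs$subject_id)
  n_correct <- sum(pred_keys %in% true_keys)
  n_pred <- length(pred_keys)
  list(
    sensitivity = if (nrow(orth) == 0L) NA_real_ else n_correct / nrow(orth),
    precision = if (n_pred == 0L) NA_real_ else n_correct / n_pred,
    n_true = nrow(orth), n_predicted = n_pred, n_correct = n_correct,
    flagged = n_pred == 0L)
}

#' Write a simulated genome pair to disk
#'
#' Writes `simA.aa/` and `simB.aa/` genome folders plus `truth.tsv` under
#' `dir` — the layout the command-line interface consumes.
#'
#' @param sim Result of [simulate_genome_pair()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_pair <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_db(sim$A, dir)
  write_genome_db(sim$B, dir)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
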