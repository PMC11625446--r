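#' Analysis configuration
#'
#' Bundles the parameters of the full pipeline. Defaults are the study-scale
#' settings: distances 0-100, 1000 permutations, 100 Markov null sequences
#' per individual, community experiment of 500 sequences of 1000 elements,
#' AICc tie threshold 2.0, and exclusion of corpora under 200 tokens (small
#' samples make entropy estimation unreliable). `desk = TRUE` switches to a
#' reduced preset (n_perm = 200, n_sims = 25, community 50 sequences) for
#' interactive work.
#'
#' @param d_max maximum inter-element distance (default 100).
#' @param n_perm permutation replicates (default 1000).
#' @param tie_threshold AICc tie threshold (default 2.0).
#' @param condensed also analyse the condensed variant (default TRUE).
#' @param run_null run per-individual Markov null distributions (default
#'   TRUE).
#' @param n_sims Markov null sequences per individual (default 100).
#' @param community_n_sequences,community_sim_length community experiment
#'   size (defaults 500 and 1000).
#' @param min_corpus_tokens exclusion threshold (default 200).
#' @param seed master integer seed.
#' @param desk use the reduced desk-scale preset.
#' @return list of class `run_config`.
#' @export
run_config <- function(d_max = 100L, n_perm = 1000L, tie_threshold = 2.0,
                       condensed = TRUE, run_null = TRUE, n_sims = 100L,
                       community_n_sequences = 500L,
                       community_sim_length = 1000L,
                       min_corpus_tokens = 200L, seed = 1L, desk = FALSE) {
  if (desk) {
    n_perm <- 200L; n_sims <- 25L; community_n_sequences <- 50L
  }
  structure(
    list(d_max = as.integer(d_max), n_perm = as.integer(n_perm),
         tie_threshold = tie_threshold, condensed = condensed,
         run_null = run_null, n_sims = as.integer(n_sims),
         community_n_sequences = as.integer(community_n_sequences),
         community_sim_length = as.integer(community_sim_length),
         min_corpus_tokens = as.integer(min_corpus_tokens),
         seed = as.integer(seed), desk = desk),
    class = "run_config"
  )
}

analyse_variant <- function(stream, config, seed) {
  curve <- estimate_decay_curve(stream,
                                d_max = min(config$d_max, stream$N - 1L),
                                n_perm = config$n_perm, seed = seed)
  sel <- select_decay_model(curve, config$tie_threshold)
  trans <- NULL
  comp <- sel$fits$composite
  if (!is.null(sel$comparison) &&
      "composite" %in% sel$comparison$best_set &&
      isTRUE(comp$converged) &&
      comp$coefficients[["a"]] > 0 && comp$coefficients[["c"]] > 0) {
    trans <- tryCatch(
      suppressWarnings(transition_point(comp, sel$max_distance$distance)),
      error = function(e) NULL)
  }
  nullres <- NULL
  if (config$run_null) {
    chain <- fit_markov(stream)
    nullres <- null_max_distance(chain, stream$N,
                                 observed_max = sel$max_distance$distance,
                                 n_sims = config$n_sims,
                                 d_max = config$d_max,
                                 n_perm = config$n_perm,
                                 seed = seed + 1L)
  }
  list(curve = curve, max_distance = sel$max_distance, fits = sel$fits,
       comparison = sel$comparison, transition = trans, null = nullres)
}

#' Run the full analysis for one individual
#'
#' Produces, for the raw and (optionally) condensed streams: the MI decay
#' curve, maximum dependency distance, three-family fit and AICc comparison,
#' the transition point when the composite model is among the best set, and
#' the Markov-chain null verdict. Corpora below the minimum token count are
#' excluded (entropy estimation from small samples carries high error) and
#' returned with `excluded = TRUE`.
#'
#' @param corpus an `action_corpus`.
#' @param config a `run_config`.
#' @return list of class `individual_result` with elements `individual`,
#'   `summary`, `excluded`, `raw`, `condensed` (NULL when disabled).
#' @export
run_individual <- function(corpus, config = run_config()) {
  stopifnot(inherits(corpus, "action_corpus"))
  summ <- summarize_corpus(corpus)
  if (corpus$stream$N < config$min_corpus_tokens) {
    message(corpus$individual_id, ": fewer than ", config$min_corpus_tokens,
            " actions; omitted from MI analyses")
    return(structure(list(individual = corpus$individual_id, summary = summ,
                          excluded = TRUE, raw = NULL, condensed = NULL),
                     class = "individual_result"))
  }
  # per-individual seed offset stable under list reordering
  base_seed <- config$seed + sum(utf8ToInt(corpus$individual_id)) %% 10000L
  raw <- analyse_variant(corpus$stream, config, seed = base_seed)
  cond <- if (config$condensed) {
    analyse_variant(condense(corpus$stream), config, seed = base_seed + 2L)
  }
  structure(list(individual = corpus$individual_id, summary = summ,
                 excluded = FALSE, raw = raw, condensed = cond),
            class = "individual_result")
}

#' Cross-individual mean and sample SD of maximum dependency distances
#'
#' SDs use the sample (n - 1) denominator. When any individual's range is
#' censored at d_max, a second mean/SD pair excluding censored individuals
#' is reported (a censored range is a lower bound, so including it biases
#' the mean).
#'
#' @param distances integer vector of per-individual maximum distances.
#' @param censored logical vector flagging censored ranges.
#' @return list `mean_all`, `sd_all`, `n_all`, `mean_uncensored`,
#'   `sd_uncensored`, `n_uncensored`.
#' @export
max_distance_summary <- function(distances, censored = rep(FALSE, length(distances))) {
  u <- distances[!censored]
  list(mean_all = mean(distances), sd_all = stats::sd(distances),
       n_all = length(distances),
       mean_uncensored = mean(u), sd_uncensored = stats::sd(u),
       n_uncensored = length(u))
}

#' Run the full study across individuals
#'
#' @param corpora named list of `action_corpus` objects.
#' @param config a `run_config`.
#' @param community also run the community Markov experiment (default FALSE;
#'   it is by far the most expensive stage).
#' @return list of class `study_report`: `individuals` (per-individual
#'   results), `summary_table` (corpus descriptives), `selection_table`
#'   (per-individual, per-variant model preference, max distance, transition,
#'   null verdict), `model_table` (AICc rows for the condensed variant,
#'   mirroring a published selection-table layout), `aggregates`
#'   (cross-individual means/SDs), `community` (when requested), `config`.
#' @export
run_study <- function(corpora, config = run_config(), community = FALSE) {
  if (length(corpora) == 0L) stop("empty study: no corpora", call. = FALSE)
  results <- lapply(corpora, run_individual, config = config)
  names(results) <- vapply(results, `[[`, character(1), "individual")
  summary_table <- do.call(rbind, lapply(results, `[[`, "summary"))
  rownames(summary_table) <- NULL
  included <- Filter(function(r) !r$excluded, results)
  sel_rows <- lapply(included, function(r) {
    variant_row <- function(v, label) {
      if (is.null(v)) return(NULL)
      data.frame(
        individual = r$individual, variant = label,
        max_distance = v$max_distance$distance,
        censored = v$max_distance$censored,
        preferred_model = if (!is.null(v$comparison)) {
          if (!is.na(v$comparison$sole_best)) v$comparison$sole_best
          else paste(v$comparison$best_set, collapse = "|")
        } else NA_character_,
        transition_point = if (!is.null(v$transition))
          v$transition$transition_distance else NA_integer_,
        null_verdict = if (!is.null(v$null)) v$null$verdict else NA_character_,
        null_mean = if (!is.null(v$null)) v$null$mean else NA_real_,
        null_ci_lower = if (!is.null(v$null)) v$null$ci_lower else NA_real_,
        null_ci_upper = if (!is.null(v$null)) v$null$ci_upper else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    rbind(variant_row(r$raw, "raw"), variant_row(r$condensed, "condensed"))
  })
  selection_table <- do.call(rbind, sel_rows)
  rownames(selection_table) <- NULL
  model_rows <- lapply(included, function(r) {
    v <- if (!is.null(r$condensed)) r$condensed else r$raw
    if (is.null(v$comparison)) return(NULL)
    cbind(individual = r$individual,
          max_element_distance = v$max_distance$distance,
          v$comparison$table)
  })
  model_table <- do.call(rbind, model_rows)
  rownames(model_table) <- NULL
  agg <- list()
  for (variant in unique(selection_table$variant)) {
    st <- selection_table[selection_table$variant == variant, ]
    agg[[variant]] <- max_distance_summary(st$max_distance, st$censored)
    tp <- st$transition_point[!is.na(st$transition_point)]
    agg[[variant]]$mean_transition <- if (length(tp)) mean(tp) else NA_real_
    agg[[variant]]$n_transition <- length(tp)
  }
  comm <- NULL
  if (community) {
    comm <- community_experiment(pool_corpora(corpora),
                                 n_sequences = config$community_n_sequences,
                                 sim_length = config$community_sim_length,
                                 d_max = config$d_max, n_perm = config$n_perm,
                                 tie_threshold = config$tie_threshold,
                                 seed = config$seed + 777L)
  }
  structure(
    list(individuals = results, summary_table = summary_table,
         selection_table = selection_table, model_table = model_table,
         aggregates = agg, community = comm, config = config),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", length(x$individuals), "individuals\n")
  print(x$selection_table)
  invisible(x)
}

#' Load the published Bossou field-study summary tables
#'
#' Returns the published per-individual summary statistics of the Bossou
#' chimpanzee nut-cracking corpus shipped with the package: corpus
#' descriptives (sequence/element/action-type/nut counts), maximum
#' dependency distances with model preferences and transition points, and
#' the condensed-variant AICc model-selection rows. The raw video-coded
#' corpus itself is not public; these printed summaries are the inputs for
#' the reporting arithmetic that the package reproduces.
#'
#' @return list of data frames `table1`, `table2`, `table3`.
#' @export
published_study_tables <- function() {
  rd <- function(f) utils::read.table(
    system.file("extdata", f, package = "midecay", mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  list(table1 = rd("bossou_table1.tsv"),
       table2 = rd("bossou_table2.tsv"),
       table3 = rd("bossou_table3.tsv"))
}

#' Reproduce cross-individual aggregates from published summary tables
#'
#' Recomputes, from the printed per-individual values, the corpus totals,
#' mean sequence lengths with Poisson-approximation SEs, cross-individual
#' means/SDs of maximum dependency distances (raw, raw excluding censored
#' individuals, condensed), the mean transition point, and per-individual
#' Akaike weights reconstructed from the printed AICc differences.
#'
#' @param tables list as returned by [published_study_tables()].
#' @return list with `totals` (nuts, actions, action-type classes),
#'   `sequence_length` (per-individual mean/se), `max_distance_raw`,
#'   `max_distance_condensed`, `mean_transition`, `weights`
#'   (per-individual-model reconstructed weights).
#' @export
published_aggregates <- function(tables = published_study_tables()) {
  t1 <- tables$table1[tables$table1$sampled, ]
  seq_len_tab <- do.call(rbind, lapply(seq_len(nrow(t1)), function(i) {
    ms <- poisson_mean_se(t1$n_elements[i], t1$n_sequences[i])
    data.frame(individual = t1$individual[i], mean = ms$mean, se = ms$se)
  }))
  t2 <- tables$table2
  raw <- max_distance_summary(t2$max_distance, t2$censored)
  t3 <- tables$table3
  cond_d <- tapply(t3$max_element_distance, t3$individual, unique)
  cond <- max_distance_summary(as.vector(cond_d))
  w <- do.call(rbind, lapply(split(t3, t3$individual), function(d) {
    d <- d[order(d$dAICc), ]
    data.frame(individual = d$individual, model = d$model,
               dAICc = d$dAICc, weight = akaike_weights(d$dAICc),
               stringsAsFactors = FALSE)
  }))
  rownames(w) <- NULL
  list(
    totals = list(nuts_cracked = sum(t1$nuts_cracked),
                  actions = sum(t1$n_elements)),
    sequence_length = seq_len_tab,
    max_distance_raw = raw,
    max_distance_condensed = cond,
    mean_transition = mean(t2$transition_point, na.rm = TRUE),
    weights = w
  )
}
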