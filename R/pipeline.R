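# Pipeline orchestration: named stages over documented on-disk artifacts
# (JSON Lines and CSV), a flat config with seeded determinism, and a thin
# command-line wrapper (inst/scripts/litkg.R) over run_subcommand().
#
# Identical config + inputs give byte-identical CSV/JSONL outputs: stages
# write through the package's stable writers and draw all randomness from
# config$seed.

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions baked into the modules: cosine
#' threshold `tau = 0.85`, walk length 4, median quadrant splits, emerging
#' top-betweenness quantile 0.25, 10 hubs, 5% validation sampling.
#'
#' @param tau cosine-similarity threshold for synonym clustering.
#' @param walk_t Walktrap walk length.
#' @param split quadrant split statistic, `"median"` or `"mean"`.
#' @param emerging_q top betweenness quantile for emerging nodes.
#' @param hub_k hub count.
#' @param sample_fraction stratified validation sampling fraction.
#' @param seed master seed for every stochastic stage.
#' @param keywords_plus include WoS Keywords Plus terms when parsing?
#' @param weighted_centrality use weighted shortest paths for centralities?
#' @param min_theme_size minimum community size kept by the strategy stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(tau = 0.85, walk_t = 4L,
                            split = c("median", "mean"),
                            emerging_q = 0.25, hub_k = 10L,
                            sample_fraction = 0.05, seed = 1L,
                            keywords_plus = FALSE,
                            weighted_centrality = FALSE,
                            min_theme_size = 3L) {
  split <- match.arg(split)
  stopifnot(tau > 0, tau <= 1, walk_t >= 1, emerging_q > 0, emerging_q <= 1,
            sample_fraction > 0, sample_fraction <= 1, min_theme_size >= 1)
  structure(list(tau = tau, walk_t = as.integer(walk_t), split = split,
                 emerging_q = emerging_q, hub_k = as.integer(hub_k),
                 sample_fraction = sample_fraction, seed = as.integer(seed),
                 keywords_plus = isTRUE(keywords_plus),
                 weighted_centrality = isTRUE(weighted_centrality),
                 min_theme_size = as.integer(min_theme_size)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  fnv1a(paste(names(config), vapply(config, format, ""), collapse = ";"))
}

log_stage <- function(name, config) {
  ver <- tryCatch(as.character(utils::packageVersion("litkg")),
                  error = function(e) "dev")
  message(sprintf("[litkg %s] stage=%s config_hash=%d seed=%d",
                  ver, name, config_hash(config), config$seed))
}

#' Run one pipeline stage
#'
#' Stages read and write the documented plain-text artifacts; no stage
#' mutates its inputs; every run logs package version, config hash, and
#' seed to stderr. Paths are given as named entries of `paths`:
#'
#' * `simulate`: writes `records` (JSONL), `embeddings` (JSONL),
#'   `triples` (JSONL) from a synthetic spec (`spec_file` optional).
#' * `parse`: `wos` and/or `nbib` input -> deduplicated `records` JSONL.
#' * `standardize`: `records` + `embeddings` -> `keyword_map` CSV.
#' * `network`: `records` + `keyword_map` -> giant-component `edges` CSV,
#'   `metrics` CSV (node centralities), optional `graphml`.
#' * `communities`: `edges` -> `partition` CSV, optional `merges` CSV.
#' * `strategy`: `edges` + `partition` -> `themes` CSV with quadrants.
#' * `kg`: `triples` (+ optional `keyword_map`) -> `kg_edges` CSV,
#'   optional `graphml`.
#' * `classify`: `triples` (+ optional `keyword_map`) ->
#'   `classification` CSV.
#' * `biblio`: `records` (+ optional `hdi`) -> `yearly` CSV,
#'   `countries` CSV.
#' * `validate`: `triples` -> stratified `sample` JSONL; with `labels_a`
#'   and `labels_b` CSVs also writes `kappa` (JSON).
#'
#' @param name stage name (see above).
#' @param config a `pipeline_config`.
#' @param paths named list of input/output file paths.
#' @return invisibly, a named list of the artifacts written.
#' @export
run_subcommand <- function(name, config = pipeline_config(), paths = list()) {
  name <- match.arg(name, c("parse", "standardize", "network", "communities",
                            "strategy", "kg", "classify", "biblio",
                            "simulate", "validate"))
  log_stage(name, config)
  need <- function(key) {
    p <- paths[[key]]
    if (is.null(p)) stop("stage '", name, "' requires a '", key, "' path")
    p
  }
  switch(name,
    simulate = {
      spec <- if (!is.null(paths$spec_file)) read_synthetic_spec(paths$spec_file)
              else synthetic_spec(seed = config$seed)
      spec$seed <- config$seed
      vocab <- gen_vocabulary(spec)
      emb <- gen_embeddings(vocab, spec)
      corpus <- gen_corpus(vocab, spec)
      triples <- gen_triples(c("inflammation", "immunity", "gut",
                               "biosensing"), spec)
      write_records_jsonl(corpus, need("records"))
      write_embeddings_jsonl(emb, need("embeddings"))
      write_triples_jsonl(triples, need("triples"))
      if (!is.null(paths$vocabulary)) {
        v <- vocab[, c("term", "group", "theme", "future", "is_canonical",
                       "freq")]
        write_csv_stable(v, paths$vocabulary)
      }
      invisible(paths)
    },
    parse = {
      recs <- list()
      if (!is.null(paths$wos))
        recs <- c(recs, list(parse_wos_export(
          readLines(paths$wos, warn = FALSE),
          keywords_plus = config$keywords_plus)))
      if (!is.null(paths$nbib))
        recs <- c(recs, list(parse_pubmed_medline(
          readLines(paths$nbib, warn = FALSE))))
      if (length(recs) == 0L) stop("stage 'parse' needs 'wos' or 'nbib' input")
      all <- do.call(rbind, recs)
      class(all) <- c("biblio_corpus", "data.frame")
      write_records_jsonl(dedupe_records(all), need("records"))
      invisible(paths)
    },
    standardize = {
      records <- read_records_jsonl(need("records"))
      provider <- if (!is.null(paths$embeddings))
        file_provider(paths$embeddings) else hash_provider()
      map <- standardize_keywords(records, provider, tau = config$tau)
      write_keyword_map(map, need("keyword_map"))
      invisible(paths)
    },
    network = {
      records <- read_records_jsonl(need("records"))
      map <- read_keyword_map(need("keyword_map"), tau = config$tau)
      net <- giant_component(build_cooccurrence(records, map))
      write_edgelist_csv(net, need("edges"))
      if (!is.null(paths$metrics))
        write_csv_stable(node_centralities(net,
          weighted = config$weighted_centrality), paths$metrics)
      if (!is.null(paths$graphml)) write_graphml(net, paths$graphml)
      invisible(paths)
    },
    communities = {
      net <- read_edgelist_csv(need("edges"))
      part <- walktrap_communities(net, t = config$walk_t)
      write_partition_csv(part, need("partition"), merges_path = paths$merges)
      invisible(paths)
    },
    strategy = {
      net <- read_edgelist_csv(need("edges"))
      assignment <- read_partition_csv(need("partition"))
      metrics <- theme_metrics(net, assignment,
                               min_size = config$min_theme_size)
      if (nrow(metrics) == 0L)
        stop("no theme of size >= ", config$min_theme_size, " to classify")
      metrics <- classify_quadrants(metrics, split = config$split)
      write_theme_csv(metrics, need("themes"))
      invisible(paths)
    },
    kg = {
      triples <- read_triples_jsonl(need("triples"))
      map <- if (!is.null(paths$keyword_map))
        read_keyword_map(paths$keyword_map, tau = config$tau) else NULL
      kg <- assemble_kg(normalize_entities(triples, map))
      net <- kg_as_network(kg)
      write_edgelist_csv(net, need("kg_edges"))
      if (!is.null(paths$graphml)) write_graphml(net, paths$graphml)
      invisible(paths)
    },
    classify = {
      triples <- read_triples_jsonl(need("triples"))
      map <- if (!is.null(paths$keyword_map))
        read_keyword_map(paths$keyword_map, tau = config$tau) else NULL
      kg <- assemble_kg(normalize_entities(triples, map))
      cls <- classify_nodes(kg, hub_k = config$hub_k,
                            emerging_q = config$emerging_q,
                            weighted = config$weighted_centrality)
      write_classification_csv(cls, need("classification"))
      invisible(paths)
    },
    biblio = {
      records <- read_records_jsonl(need("records"))
      trend <- annual_trend(records)
      write_csv_stable(trend$yearly, need("yearly"))
      hdi <- if (!is.null(paths$hdi)) read_hdi_csv(paths$hdi) else NULL
      stats <- country_stats(records, hdi)
      write_csv_stable(stats, need("countries"))
      if (!is.null(paths$trend))
        writeLines(as.character(jsonlite::toJSON(
          list(slope = trend$slope, intercept = trend$intercept),
          auto_unbox = TRUE, digits = NA)), paths$trend)
      invisible(paths)
    },
    validate = {
      triples <- read_triples_jsonl(need("triples"))
      smp <- stratified_sample(triples, fraction = config$sample_fraction,
                               seed = config$seed)
      write_triples_jsonl(smp, need("sample"))
      if (!is.null(paths$labels_a) && !is.null(paths$labels_b)) {
        la <- read_csv_stable(paths$labels_a)[[1]]
        lb <- read_csv_stable(paths$labels_b)[[1]]
        kappa <- cohens_kappa(la, lb)
        writeLines(as.character(jsonlite::toJSON(list(kappa = kappa),
          auto_unbox = TRUE, digits = NA)), need("kappa"))
      }
      invisible(paths)
    })
}

#' Run the full synthetic analysis pipeline in a directory
#'
#' Convenience wrapper chaining simulate, standardize, network,
#' communities, strategy, kg, classify, biblio, and validate with default
#' artifact names inside `dir`. Used by tests and the worked example.
#'
#' @param dir output directory (created if needed).
#' @param config a `pipeline_config`.
#' @return named list of artifact paths.
#' @export
run_pipeline <- function(dir, config = pipeline_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  paths <- list(records = p("records.jsonl"),
                embeddings = p("embeddings.jsonl"),
                triples = p("triples.jsonl"),
                vocabulary = p("vocabulary.csv"),
                keyword_map = p("keyword_map.csv"),
                edges = p("edges.csv"),
                metrics = p("node_metrics.csv"),
                partition = p("partition.csv"),
                merges = p("merges.csv"),
                themes = p("themes.csv"),
                kg_edges = p("kg_edges.csv"),
                classification = p("classification.csv"),
                yearly = p("yearly.csv"),
                countries = p("countries.csv"),
                trend = p("trend.json"),
                sample = p("validation_sample.jsonl"))
  for (stage in c("simulate", "standardize", "network", "communities",
                  "strategy", "kg", "classify", "biblio", "validate"))
    run_subcommand(stage, config, paths)
  invisible(paths)
}
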