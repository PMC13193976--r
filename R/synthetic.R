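# Synthetic corpora, embeddings, triples, and annotation pairs with the
# planted structure the downstream stages assume: synonym groups that are
# tight clusters in embedding space, records whose keyword co-occurrence
# carries planted community structure including low-density/high-centrality
# "future themes", triple sets with planted hub / bridge / emerging
# entities, and paired annotator labels with a target agreement level.
#
# All generators draw from named child streams of a single integer seed
# (see child_seed()), so each stage is bit-reproducible and independently
# regenerable.

#' Specification of a synthetic corpus
#'
#' Defaults describe a desk-scale corpus with recoverable structure:
#' 10 core themes sharing 40 synonym groups plus 2 single-group future
#' themes, 500 records of 3-6 keywords, a 5% cross-theme keyword rate,
#' and an embedding geometry with within-group cosine >= 0.9 and
#' between-group cosine <= 0.6 (so the default threshold 0.85 separates
#' groups exactly). Future themes must stay a minority relative to core
#' themes -- fewer than half as many -- for their planted
#' low-density/high-centrality signature to survive the modularity cut
#' (see the methods vignette for the argument).
#'
#' @param n_groups total synonym groups (>= n_themes + n_future_themes).
#' @param group_size_range integer pair: min/max terms per group.
#' @param n_themes planted core co-occurrence communities.
#' @param n_future_themes planted low-density/high-centrality themes, one
#'   synonym group each.
#' @param n_records corpus size.
#' @param keywords_per_record integer pair: keywords drawn per record.
#' @param cross_theme_rate probability a keyword slot is drawn from a
#'   foreign core theme.
#' @param embed_dim embedding dimension (>= 8).
#' @param within_sim target minimum within-group cosine, in (0, 1].
#' @param between_sim maximum allowed between-group cosine, in [0, 1);
#'   must be strictly below `within_sim`.
#' @param seed master integer seed.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_groups = 42L, group_size_range = c(2L, 4L),
                           n_themes = 10L, n_future_themes = 2L,
                           n_records = 500L, keywords_per_record = c(3L, 6L),
                           cross_theme_rate = 0.05, embed_dim = 32L,
                           within_sim = 0.9, between_sim = 0.6, seed = 1L) {
  spec <- list(n_groups = as.integer(n_groups),
               group_size_range = as.integer(group_size_range),
               n_themes = as.integer(n_themes),
               n_future_themes = as.integer(n_future_themes),
               n_records = as.integer(n_records),
               keywords_per_record = as.integer(keywords_per_record),
               cross_theme_rate = cross_theme_rate,
               embed_dim = as.integer(embed_dim),
               within_sim = within_sim, between_sim = between_sim,
               seed = as.integer(seed))
  counts <- c(spec$n_groups, spec$n_themes, spec$n_records, spec$embed_dim)
  if (any(counts <= 0L)) stop("all counts must be positive")
  if (spec$n_future_themes < 0L) stop("n_future_themes must be >= 0")
  if (spec$group_size_range[1] > spec$group_size_range[2])
    stop("group_size_range is inverted")
  if (spec$group_size_range[1] < 1L) stop("group sizes must be >= 1")
  if (spec$keywords_per_record[1] > spec$keywords_per_record[2])
    stop("keywords_per_record range is inverted")
  if (spec$cross_theme_rate < 0 || spec$cross_theme_rate > 1)
    stop("cross_theme_rate must lie in [0, 1]")
  if (!(spec$within_sim > 0 && spec$within_sim <= 1) ||
      spec$between_sim < 0 || spec$between_sim >= 1)
    stop("similarity bounds out of range")
  if (spec$within_sim <= spec$between_sim)
    stop("within_sim must exceed between_sim (groups would be inseparable)")
  if (spec$n_groups < spec$n_themes + spec$n_future_themes)
    stop("need at least one group per theme")
  structure(spec, class = "synthetic_spec")
}

#' Read a synthetic spec from a key=value or JSON config file
#'
#' @param path config file; keys are `synthetic_spec` argument names.
#' @return a `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (grepl("^\\s*\\{", txt)) {
    jsonlite::fromJSON(txt)
  } else {
    kv <- read_key_values(path)
    lapply(kv, function(v) {
      n <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
      if (any(is.na(n))) v else n
    })
  }
  do.call(synthetic_spec, vals[names(vals) %in% names(formals(synthetic_spec))])
}

read_key_values <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(vals) <- vapply(kv, function(p) trimws(p[[1]]), "")
  vals
}

#' Generate a synonym-group vocabulary
#'
#' Allocates groups to themes (future themes get exactly one group each;
#' the rest are dealt round-robin to core themes), draws a group size from
#' `group_size_range`, and assigns planted frequencies in which each
#' group's canonical term is strictly the most frequent (canonicals draw
#' from 30-45, variants from 1-10). Deterministic under the spec seed.
#'
#' @param spec a `synthetic_spec`.
#' @return data.frame(term, group, theme, future, is_canonical, freq)
#'   where `theme` is `"core<i>"` or `"future<i>"`.
#' @export
gen_vocabulary <- function(spec) {
  with_seed(child_seed(spec$seed, "vocabulary"), {
    n_core_groups <- spec$n_groups - spec$n_future_themes
    theme_of_group <- c(
      if (spec$n_future_themes > 0L)
        paste0("future", seq_len(spec$n_future_themes)),
      paste0("core", rep_len(seq_len(spec$n_themes), n_core_groups)))
    future_of_group <- startsWith(theme_of_group, "future")
    rows <- lapply(seq_len(spec$n_groups), function(g) {
      sizes <- seq.int(spec$group_size_range[1], spec$group_size_range[2])
      size <- sizes[[sample.int(length(sizes), 1L)]]
      terms <- sprintf("kw%02d%s", g, letters[seq_len(size)])
      freq <- c(sample(30:45, 1L), sample(1:10, size - 1L, replace = TRUE))
      data.frame(term = terms, group = g, theme = theme_of_group[[g]],
                 future = future_of_group[[g]],
                 is_canonical = c(TRUE, rep(FALSE, size - 1L)),
                 freq = freq, stringsAsFactors = FALSE)
    })
    vocab <- do.call(rbind, rows)
    rownames(vocab) <- NULL
    vocab
  })
}

#' Generate embeddings with planted group geometry
#'
#' One random unit base vector per group; members are
#' `normalize(base + sigma * noise)` with `sigma` chosen from the target
#' within-group cosine. Generation is retried (redrawing bases and noise,
#' shrinking `sigma`) until the realized geometry satisfies both bounds --
#' minimum within-group pairwise cosine >= `within_sim` and maximum
#' between-group cosine <= `between_sim` -- and errors after a bounded
#' number of attempts if the bounds are unattainable in `embed_dim`.
#'
#' @param vocabulary output of [gen_vocabulary()].
#' @param spec a `synthetic_spec` with `embed_dim >= 8`.
#' @param max_attempts retry bound.
#' @return a term-by-dimension matrix with unit L2 rows, rownames = terms.
#' @export
gen_embeddings <- function(vocabulary, spec, max_attempts = 60L) {
  if (spec$embed_dim < 8L) stop("embed_dim must be at least 8")
  d <- spec$embed_dim
  groups <- split(vocabulary$term, vocabulary$group)
  # target a realized cosine comfortably above the bound; the expected
  # cosine of two members is ~ 1 / (1 + s^2) where s is the total noise
  # norm, so s = sqrt(1/target - 1), spread over d coordinates
  target <- spec$within_sim + 0.6 * (1 - spec$within_sim)
  sigma0 <- sqrt(1 / target - 1) / sqrt(d)
  with_seed(child_seed(spec$seed, "embeddings"), {
    for (attempt in seq_len(max_attempts)) {
      sigma <- sigma0 * 0.9^((attempt - 1L) %/% 10L)
      bases <- matrix(stats::rnorm(length(groups) * d), ncol = d)
      if (d >= length(groups)) {
        # a random orthonormal frame: each base is still uniform on the
        # sphere, but between-group cosines start at exactly 0
        q <- qr.Q(qr(t(bases)))
        bases <- t(q) * sign(diag(qr.R(qr(t(bases)))))
      }
      bases <- bases / sqrt(rowSums(bases^2))
      mat <- do.call(rbind, lapply(seq_along(groups), function(gi) {
        k <- length(groups[[gi]])
        noise <- matrix(stats::rnorm(k * d, sd = sigma), ncol = d)
        v <- sweep(noise, 2L, bases[gi, ], `+`)
        v / sqrt(rowSums(v^2))
      }))
      rownames(mat) <- unlist(groups, use.names = FALSE)
      gid <- rep(seq_along(groups), lengths(groups))
      S <- mat %*% t(mat)
      same <- outer(gid, gid, `==`)
      diag(same) <- NA
      min_within <- min(S[same & !is.na(same)])
      max_between <- if (any(!same, na.rm = TRUE)) max(S[!same & !is.na(same)]) else -1
      if (min_within >= spec$within_sim && max_between <= spec$between_sim) {
        # restore vocabulary row order
        return(mat[vocabulary$term, , drop = FALSE])
      }
    }
    stop("could not realize within_sim/between_sim bounds in ", d,
         " dimensions after ", max_attempts, " attempts")
  })
}

#' Generate a synthetic bibliographic corpus
#'
#' Each record is assigned a theme (uniformly over core and future
#' themes). A core-theme record draws each keyword slot from its own
#' theme's groups with probability `1 - cross_theme_rate` and from a
#' foreign core theme otherwise. A future-theme record draws exactly one
#' keyword from the future theme's group and all remaining slots from a
#' single randomly chosen core theme -- future-theme keywords therefore
#' co-occur only with core keywords, never with each other, planting the
#' low-internal/high-external signature of a Callon fourth-quadrant theme.
#' Keywords are surfaced as variants sampled proportionally to their
#' planted frequency (exercising standardization); publication years
#' spread over `year_span` years ending 2025 with linearly increasing
#' expected counts; citation counts follow a geometric law.
#'
#' @param vocabulary output of [gen_vocabulary()].
#' @param spec a `synthetic_spec`.
#' @param year_span number of publication years (default 20).
#' @return a `biblio_corpus` with attribute `record_theme` (character
#'   vector of planted themes per record).
#' @export
gen_corpus <- function(vocabulary, spec, year_span = 20L) {
  kmax <- spec$keywords_per_record[2]
  if (nrow(vocabulary) < kmax)
    stop("vocabulary smaller than the keywords_per_record maximum")
  themes <- unique(vocabulary$theme)
  core_themes <- themes[startsWith(themes, "core")]
  future_themes <- themes[startsWith(themes, "future")]
  groups_of <- split(unique(vocabulary$group),
                     vocabulary$theme[!duplicated(vocabulary$group)])
  by_group <- split(vocabulary, vocabulary$group)
  pick_variant <- function(g) {
    v <- by_group[[as.character(g)]]
    v$term[sample.int(nrow(v), 1L, prob = v$freq)]
  }
  # sample() on a length-1 integer vector would expand it to 1:x
  samp <- function(x, k = 1L, replace = FALSE) x[sample.int(length(x), k, replace = replace)]
  countries_pool <- c("United States", "China", "Japan", "Italy",
                      "United Kingdom", "Germany", "France", "Australia")
  country_probs <- c(8, 7, 4, 3, 3, 2, 2, 1)
  years <- seq.int(2025L - year_span + 1L, 2025L)
  with_seed(child_seed(spec$seed, "corpus"), {
    # future themes are sampled at twice the per-theme rate of core themes:
    # a fourth-quadrant theme is by definition strongly tied to the core of
    # the field, and the extra external weight is what makes its planted
    # low-density/high-centrality signature identifiable by the
    # modularity cut (see the methods vignette)
    theme_pool <- c(core_themes, future_themes)
    theme_w <- c(rep(1, length(core_themes)), rep(2, length(future_themes)))
    rec_theme <- theme_pool[sample.int(length(theme_pool), spec$n_records,
                                       replace = TRUE, prob = theme_w)]
    # per-future-theme round-robin over core donor themes, so each future
    # keyword's co-occurrence weight spreads evenly over core communities
    donor_counter <- structure(integer(length(future_themes)),
                               names = future_themes)
    donor_schedule <- round_robin_pairs(length(core_themes))
    rows <- lapply(seq_len(spec$n_records), function(i) {
      th <- rec_theme[[i]]
      if (startsWith(th, "future")) {
        j <- donor_counter[[th]]
        donor_counter[[th]] <<- j + 1L
        donors <- core_themes[donor_schedule[[(j %% length(donor_schedule)) + 1L]]]
        gs <- c(groups_of[[th]][1],
                vapply(donors, function(dt) samp(groups_of[[dt]]), 0L))
      } else {
        ks <- seq.int(spec$keywords_per_record[1], kmax)
        k <- ks[[sample.int(length(ks), 1L)]]
        own <- groups_of[[th]]
        foreign <- setdiff(unlist(groups_of[core_themes]), own)
        gs <- vapply(seq_len(k), function(j) {
          if (stats::runif(1) < spec$cross_theme_rate && length(foreign) > 0L)
            samp(foreign) else samp(own)
        }, 0L)
      }
      kw <- unique(vapply(gs, pick_variant, ""))
      n_c <- sample(1:2, 1L, prob = c(0.7, 0.3))
      list(keywords = kw,
           countries = sample(countries_pool, n_c, prob = country_probs),
           year = sample(years, 1L, prob = seq_len(year_span)),
           tc = stats::rgeom(1L, prob = 0.15))
    })
    corpus <- biblio_corpus(
      record_id = sprintf("SYN-%04d", seq_len(spec$n_records)),
      title = sprintf("Synthetic record %04d (%s)",
                      seq_len(spec$n_records), rec_theme),
      abstract = "",
      year = vapply(rows, `[[`, 0L, "year"),
      source_db = "synthetic",
      keywords = lapply(rows, `[[`, "keywords"),
      times_cited = vapply(rows, `[[`, 0L, "tc"),
      countries = lapply(rows, `[[`, "countries"),
      journal = "Journal of Synthetic Bone Research")
    attr(corpus, "record_theme") <- rec_theme
    corpus
  })
}

# Tournament (circle-method) schedule of the K(n) edge set: a list of
# index pairs grouped in rounds such that every n/2 consecutive pairs
# cover each index at most once -- any prefix of the schedule touches all
# indices with counts differing by at most one. Used to spread a future
# theme's donor pairs evenly over core themes. For odd n the bye slot is
# dropped.
round_robin_pairs <- function(n) {
  if (n < 2L) return(list(c(1L, 1L)))
  m <- if (n %% 2L == 0L) n else n + 1L
  rounds <- list()
  rot <- seq_len(m - 1L)
  for (r in seq_len(m - 1L)) {
    teams <- c(m, rot)
    pairs <- lapply(seq_len(m %/% 2L), function(i) {
      sort(c(teams[[i]], teams[[m + 1L - i]]))
    })
    pairs <- Filter(function(p) all(p <= n), pairs)
    rounds <- c(rounds, pairs)
    rot <- c(rot[-1], rot[1])
  }
  rounds
}

#' Generate entity-relation triples with planted topology
#'
#' Per domain: a planted hub wired to every member of a 10-entity core
#' clique and to 3 leaf entities (so the hub has strictly maximal degree
#' in its domain); a 4-entity satellite clique reachable from the core
#' only through a planted emerging entity of degree 2 -- the sole cut
#' vertex on the only path joining the two clusters, hence below-median
#' degree and top-ranked betweenness. Consecutive domains are joined by
#' planted bridge entities that receive one triple in each of the two
#' domains. Predicates are drawn from [MOCK_VERBS]; everything else is
#' structural and deterministic under the seed.
#'
#' @param domains character vector of domain tags (>= 2 when bridges are
#'   requested).
#' @param spec a `synthetic_spec` (only its seed is used).
#' @param n_bridges number of planted bridge entities (default one per
#'   consecutive domain pair).
#' @return triple data.frame with attribute `planted` = list(hubs,
#'   bridges, emerging) of entity names.
#' @export
gen_triples <- function(domains, spec = synthetic_spec(),
                        n_bridges = max(length(domains) - 1L, 0L)) {
  if (n_bridges > 0L && length(domains) < 2L)
    stop("bridges require at least 2 domains")
  n_core <- 10L; n_sat <- 4L; n_leaf <- 3L
  with_seed(child_seed(spec$seed, "triples"), {
    pred <- function() sample(MOCK_VERBS, 1L)
    rows <- list()
    add <- function(s, p, o, d) {
      rows[[length(rows) + 1L]] <<- list(subject = s, predicate = p,
                                         object = o, domain = d)
    }
    hubs <- character(0); emergings <- character(0)
    for (d in domains) {
      hub <- paste0(d, "_hub"); hubs <- c(hubs, hub)
      cores <- sprintf("%s_core%02d", d, seq_len(n_core))
      sats <- sprintf("%s_sat%d", d, seq_len(n_sat))
      leaves <- sprintf("%s_leaf%d", d, seq_len(n_leaf))
      emg <- paste0(d, "_emerging"); emergings <- c(emergings, emg)
      for (cc in cores) add(hub, pred(), cc, d)
      for (lf in leaves) add(hub, pred(), lf, d)
      for (i in seq_len(n_core - 1L)) for (j in seq.int(i + 1L, n_core))
        add(cores[[i]], pred(), cores[[j]], d)
      for (i in seq_len(n_sat - 1L)) for (j in seq.int(i + 1L, n_sat))
        add(sats[[i]], pred(), sats[[j]], d)
      add(cores[[1]], pred(), emg, d)   # core1 - emg - sat1 is the only
      add(emg, pred(), sats[[1]], d)    # passage between the two clusters
    }
    bridges <- character(0)
    for (bi in seq_len(n_bridges)) {
      i <- ((bi - 1L) %% (length(domains) - 1L)) + 1L
      br <- sprintf("bridge%02d", bi); bridges <- c(bridges, br)
      add(br, pred(), paste0(domains[[i]], "_hub"), domains[[i]])
      add(br, pred(), paste0(domains[[i + 1L]], "_hub"), domains[[i + 1L]])
    }
    df <- data.frame(
      subject = vapply(rows, `[[`, "", "subject"),
      predicate = vapply(rows, `[[`, "", "predicate"),
      object = vapply(rows, `[[`, "", "object"),
      domain = vapply(rows, `[[`, "", "domain"),
      source_id = sprintf("TRI-%04d", seq_along(rows)),
      stringsAsFactors = FALSE)
    attr(df, "planted") <- list(hubs = hubs, bridges = bridges,
                                emerging = emergings)
    df
  })
}

#' Generate a pair of annotator label vectors with target agreement
#'
#' A balanced latent binary truth is drawn; annotator A reports it
#' faithfully and annotator B agrees with A independently per item with
#' probability `agreement`. For this symmetric binary design the expected
#' Cohen's kappa is `2 * agreement - 1`.
#'
#' @param n number of items.
#' @param agreement agreement probability in `[0.5, 1]`.
#' @param seed integer seed.
#' @return list with integer vectors `a` and `b` (0/1 labels).
#' @export
gen_annotation_pair <- function(n, agreement, seed = 1L) {
  if (agreement < 0.5 || agreement > 1)
    stop("agreement must lie in [0.5, 1]")
  with_seed(child_seed(seed, "annotation"), {
    truth <- stats::rbinom(n, 1L, 0.5)
    flip <- stats::rbinom(n, 1L, 1 - agreement)
    list(a = truth, b = as.integer(xor(truth, flip)))
  })
}
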