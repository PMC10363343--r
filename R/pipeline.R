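#' Specification of a Mapper parameter sweep
#'
#' Domains for the three Mapper tunables plus the filter configuration.  The
#' grid is the Cartesian product of the three domains; the full study sweep
#' uses `{10, 15, 20} x {30, 40, 50, 60} x {5, 10, 15, 20}` = 48 triples.
#'
#' @param n_intervals,overlap_pct,n_clusters Numeric vectors of domain
#'   values.
#' @param filter_method,filter_seed Filter (lens) configuration shared by
#'   every triple.
#' @return An object of class `sweep_spec`.
#' @examples
#' sweep_spec()  # the full 48-triple study grid
#' @export
sweep_spec <- function(n_intervals = c(10, 15, 20),
                       overlap_pct = c(30, 40, 50, 60),
                       n_clusters = c(5, 10, 15, 20),
                       filter_method = c("pca", "tsne"),
                       filter_seed = 1L) {
  filter_method <- match.arg(filter_method)
  if (!length(n_intervals) || !length(overlap_pct) || !length(n_clusters)) {
    abort("every parameter domain must be nonempty.", class = "usage_error")
  }
  structure(
    list(n_intervals = sort(unique(as.numeric(n_intervals))),
         overlap_pct = sort(unique(as.numeric(overlap_pct))),
         n_clusters = sort(unique(as.numeric(n_clusters))),
         filter_method = filter_method,
         filter_seed = as.integer(filter_seed)),
    class = "sweep_spec")
}

#' Enumerate the Mapper parameter grid
#'
#' @param spec A [sweep_spec()].
#' @return A tibble `n_intervals`, `overlap_pct`, `n_clusters`, one row per
#'   triple, sorted lexicographically by the triple.
#' @examples
#' nrow(enumerate_grid(sweep_spec()))  # 48
#' @export
enumerate_grid <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  tidyr::expand_grid(n_intervals = spec$n_intervals,
                     overlap_pct = spec$overlap_pct,
                     n_clusters = spec$n_clusters) |>
    arrange(.data$n_intervals, .data$overlap_pct, .data$n_clusters)
}

#' Run the Mapper sweep over a cohort
#'
#' For every subject and parameter triple: preprocess the subject's two
#' paradigm blocks into an analysis matrix, build the Mapper graph (the 2D
#' lens is computed once per subject and reused across triples), label
#' nodes by paradigm dominance, compute the requested centralities and
#' their per-paradigm means, detect communities and compute modularity.
#' Failures are isolated per (subject, triple) and recorded in the manifest
#' with a reason instead of aborting the sweep.
#'
#' @param cohort Tibble with columns `subject` and `sessions` (list-column
#'   of two [labeled_ts()] blocks), as from [generate_cohort()].
#' @param spec A [sweep_spec()].
#' @param measures Centrality measures to compute.
#' @param strict If `TRUE`, a disconnected Mapper graph is recorded as a
#'   skipped run; the default restricts analysis to the largest connected
#'   component.
#' @param keep_graphs Keep each run's `mapper_graph` (needed by
#'   [export_outputs()] for GraphML; off by default to save memory).
#' @param target_rate Optional resampling rate passed to
#'   [preprocess_subject()].
#' @return A `mapper_sweep`: list with `manifest` (one row per subject and
#'   triple: node/edge counts, connectivity, modularity, status),
#'   `summaries` (per-subject per-triple per-measure paradigm mean
#'   centralities), `graphs` (when kept) and the `spec`.
#' @export
run_sweep <- function(cohort, spec,
                      measures = c("degree", "eigenvector", "betweenness",
                                   "closeness"),
                      strict = FALSE, keep_graphs = FALSE,
                      target_rate = NULL) {
  stopifnot(inherits(spec, "sweep_spec"),
            all(c("subject", "sessions") %in% names(cohort)))
  measures <- match.arg(measures, several.ok = TRUE)
  grid <- enumerate_grid(spec)
  paradigms <- attr(cohort, "paradigms") %||%
    unique(unlist(purrr::map(cohort$sessions[[1]], function(s) unique(s$paradigm))))

  manifest <- list(); summaries <- list(); graphs <- list()
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort$subject[i]
    am <- preprocess_subject(cohort$sessions[[i]], target_rate = target_rate)
    base_params <- mapper_params(
      grid$n_intervals[1], grid$overlap_pct[1], grid$n_clusters[1],
      filter_method = spec$filter_method, filter_seed = spec$filter_seed)
    embedding <- compute_filter(am, base_params)

    for (j in seq_len(nrow(grid))) {
      params <- mapper_params(grid$n_intervals[j], grid$overlap_pct[j],
                              grid$n_clusters[j],
                              filter_method = spec$filter_method,
                              filter_seed = spec$filter_seed)
      run <- tryCatch({
        graph <- run_mapper(am, params, embedding = embedding)
        connected <- igraph::count_components(graph$graph) == 1
        if (strict && !connected) {
          abort("disconnected Mapper graph in strict mode.",
                class = "disconnected_graph")
        }
        dominance <- label_nodes(graph, am$paradigm)
        cent <- purrr::map(measures, function(ms) {
          sc <- withr::with_options(
            list(warn = -1),
            node_centrality(graph, ms, on_disconnected = "largest_component"))
          suppressWarnings(
            paradigm_mean_centrality(sc, dominance, paradigms = paradigms,
                                     subject = subj, measure = ms))
        }) |> bind_rows()
        comm <- detect_communities(graph)
        q <- graph_modularity(graph, comm)
        list(graph = graph, connected = connected, cent = cent, q = q)
      }, error = function(e) e)

      key <- tibble(subject = subj,
                    n_intervals = grid$n_intervals[j],
                    overlap_pct = grid$overlap_pct[j],
                    n_clusters = grid$n_clusters[j])
      if (inherits(run, "error")) {
        manifest[[length(manifest) + 1]] <- key |>
          mutate(n_nodes = NA_integer_, n_edges = NA_integer_,
                 connected = NA, modularity = NA_real_,
                 status = "skipped", reason = conditionMessage(run))
      } else {
        manifest[[length(manifest) + 1]] <- key |>
          mutate(n_nodes = igraph::vcount(run$graph$graph),
                 n_edges = igraph::ecount(run$graph$graph),
                 connected = run$connected, modularity = run$q,
                 status = "ok", reason = NA_character_)
        summaries[[length(summaries) + 1]] <-
          dplyr::bind_cols(run$cent,
                           key[rep(1, nrow(run$cent)), -1, drop = FALSE])
        if (keep_graphs) {
          graphs[[paste(subj, grid$n_intervals[j], grid$overlap_pct[j],
                        grid$n_clusters[j], sep = "_")]] <- run$graph
        }
      }
    }
  }
  structure(
    list(manifest = bind_rows(manifest), summaries = bind_rows(summaries),
         graphs = graphs, spec = spec, paradigms = paradigms),
    class = "mapper_sweep")
}

#' @export
print.mapper_sweep <- function(x, ...) {
  cat(sprintf("<mapper_sweep> %d runs (%d ok, %d skipped) over %d subjects x %d triples\n",
              nrow(x$manifest), sum(x$manifest$status == "ok"),
              sum(x$manifest$status == "skipped"),
              length(unique(x$manifest$subject)),
              nrow(dplyr::distinct(x$manifest[c("n_intervals", "overlap_pct",
                                                "n_clusters")]))))
  invisible(x)
}

#' Export sweep artifacts to files
#'
#' Writes the tidy outputs of a sweep: the manifest and per-paradigm mean
#' centralities as CSV, a JSON summary, per-run GraphML graphs (when the
#' sweep kept them) and per-subject embedding scatter CSVs.
#'
#' @param sweep A `mapper_sweep` from [run_sweep()].
#' @param dir Output directory, created if absent.
#' @param formats Subset of `"csv"`, `"json"`, `"graphml"`, `"embedding"`;
#'   an empty selection writes nothing and succeeds.
#' @return Invisibly, the character vector of files written.
#' @export
export_outputs <- function(sweep, dir,
                           formats = c("csv", "json", "graphml", "embedding")) {
  stopifnot(inherits(sweep, "mapper_sweep"))
  if (!length(formats)) return(invisible(character()))
  unknown <- setdiff(formats, c("csv", "json", "graphml", "embedding"))
  if (length(unknown)) {
    abort(paste0("unknown format(s): ", paste(unknown, collapse = ", ")),
          class = "usage_error")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  if ("csv" %in% formats) {
    f1 <- file.path(dir, "manifest.csv")
    readr::write_csv(sweep$manifest, f1)
    f2 <- file.path(dir, "centrality_summaries.csv")
    readr::write_csv(sweep$summaries, f2)
    written <- c(written, f1, f2)
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "sweep_summary.json")
    jsonlite::write_json(
      list(n_runs = nrow(sweep$manifest),
           n_ok = sum(sweep$manifest$status == "ok"),
           n_skipped = sum(sweep$manifest$status == "skipped"),
           paradigms = sweep$paradigms,
           filter = sweep$spec$filter_method,
           filter_seed = sweep$spec$filter_seed),
      f, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, f)
  }
  if ("graphml" %in% formats) {
    for (nm in names(sweep$graphs)) {
      f <- file.path(dir, paste0("graph_", nm, ".graphml"))
      write_mapper_graphml(sweep$graphs[[nm]], f)
      written <- c(written, f)
    }
  }
  if ("embedding" %in% formats) {
    done <- character()
    for (nm in names(sweep$graphs)) {
      subj <- strsplit(nm, "_")[[1]][1]
      if (subj %in% done || is.null(sweep$graphs[[nm]]$embedding)) next
      f <- file.path(dir, paste0("embedding_", subj, ".csv"))
      readr::write_csv(as_tibble(sweep$graphs[[nm]]$embedding$coords), f)
      written <- c(written, f); done <- c(done, subj)
    }
  }
  invisible(written)
}

#' Write one Mapper graph as GraphML
#'
#' Node attributes carry the member count and source bin id (and the
#' dominance label when `dominance` is supplied), so the graph re-reads
#' into any GraphML consumer with its labeling intact.
#'
#' @param graph A `mapper_graph`.
#' @param path Output file path.
#' @param dominance Optional tibble from [label_nodes()].
#' @return Invisibly, `path`.
#' @export
write_mapper_graphml <- function(graph, path, dominance = NULL) {
  stopifnot(inherits(graph, "mapper_graph"))
  g <- graph$graph
  if (!is.null(dominance)) {
    igraph::V(g)$dominant <- dominance$label[match(seq_len(igraph::vcount(g)),
                                                  dominance$node)]
    igraph::V(g)$fraction <- dominance$fraction[match(seq_len(igraph::vcount(g)),
                                                      dominance$node)]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Serialize a Mapper graph with full member lists as JSON
#'
#' @param graph A `mapper_graph`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mapper_json <- function(graph, path) {
  stopifnot(inherits(graph, "mapper_graph"))
  edges <- igraph::as_edgelist(graph$graph, names = FALSE)
  jsonlite::write_json(
    list(n_points = graph$n_points,
         nodes = purrr::pmap(graph$nodes, function(node, bin, size, members) {
           list(node = node, bin = bin, size = size, members = members)
         }),
         edges = if (nrow(edges)) apply(edges, 1, as.list) else list()),
    path, auto_unbox = TRUE)
  invisible(path)
}
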