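#' Read a dendritic reconstruction from an SWC file
#'
#' Parses the standard 7-column SWC dialect (id, type, x, y, z, radius,
#' parent) used for Neurolucida-style reconstructions. Node ids are
#' re-indexed contiguously (1..n) and parent references resolved after the
#' full file is read, so forward references are accepted. Soma nodes are
#' identified by type code 1. Branch orders are always recomputed from
#' topology (see \code{\link{assign_branch_orders}}), never read from file.
#'
#' @param path Path to an SWC file.
#'
#' @return An object of class \code{morph_tree}: a list with \code{nodes}
#'   (data.frame id, type, x, y, z, radius, parent — parent is the
#'   re-indexed row of the parent node, or \code{NA} for roots),
#'   \code{soma_ids} (rows of type-1 nodes) and \code{root} (row index of
#'   the tree root).
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("SWC format error: no records in ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 7)) {
    stop("SWC format error: every record must have 7 columns")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  nodes <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  if (anyDuplicated(nodes$id)) {
    stop("SWC format error: duplicate node id(s) ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  self_par <- nodes$id[nodes$id == nodes$parent]
  if (length(self_par)) {
    stop("SWC format error: node(s) ", paste(self_par, collapse = ", "),
         " listed as their own parent (cycle)")
  }
  idx <- match(nodes$parent, nodes$id)  # NA for parent = -1 (or missing)
  if (any(is.na(idx) & nodes$parent != -1)) {
    stop("SWC format error: parent id(s) ",
         paste(nodes$parent[is.na(idx) & nodes$parent != -1], collapse = ", "),
         " not defined in file")
  }
  nodes$parent <- idx
  morph_tree(nodes, original_ids = nodes$id)
}

#' Construct a morphology tree
#'
#' @param nodes data.frame with columns id, type, x, y, z, radius, parent;
#'   \code{parent} holds the row index of the parent node (\code{NA} for a
#'   root). Type code 1 marks soma nodes, 3 dendrite.
#' @param original_ids Optional vector of the ids as found on disk (used in
#'   error messages and when writing back).
#'
#' @return An object of class \code{morph_tree}.
#' @export
morph_tree <- function(nodes, original_ids = nodes$id) {
  n <- nrow(nodes)
  nodes$id <- seq_len(n)
  # cycle check: follow parents from every node; a walk longer than n is a cycle
  for (i in seq_len(n)) {
    j <- i
    steps <- 0L
    while (!is.na(nodes$parent[j])) {
      j <- nodes$parent[j]
      steps <- steps + 1L
      if (steps > n) {
        stop("SWC format error: cyclic parent links involving node ",
             original_ids[i])
      }
    }
  }
  roots <- which(is.na(nodes$parent))
  if (!length(roots)) stop("SWC format error: no root node")
  soma_ids <- which(nodes$type == 1L)
  nonsoma_roots <- setdiff(roots, soma_ids)
  if (length(nonsoma_roots) > 0 && length(roots) > 1) {
    stop("SWC format error: multiple roots among dendrite nodes (ids ",
         paste(original_ids[nonsoma_roots], collapse = ", "), ")")
  }
  structure(
    list(nodes = nodes, soma_ids = soma_ids, root = roots[1],
         original_ids = original_ids),
    class = "morph_tree"
  )
}

#' @export
print.morph_tree <- function(x, ...) {
  cat(sprintf("<morph_tree> %d nodes (%d soma), %d leaves\n",
              nrow(x$nodes), length(x$soma_ids),
              sum(!(x$nodes$id %in% x$nodes$parent))))
  invisible(x)
}

#' Write a morphology tree to SWC
#'
#' @param tree A \code{\link{morph_tree}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_swc <- function(tree, path) {
  nd <- tree$nodes
  parent <- ifelse(is.na(nd$parent), -1L, nd$parent)
  txt <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                 nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, parent)
  writeLines(c("# SWC written by sparsegc", txt), path)
  invisible(path)
}

#' Read animal tracking from CSV
#'
#' Accepts the two-LED dialect (columns \code{t,x1,y1,x2,y2}) or the
#' single-position dialect (\code{t,x,y}). With two LEDs the animal position
#' is the midpoint of the LEDs; frames with any missing LED coordinate are
#' flagged invalid and excluded from downstream analysis (missing frames are
#' never interpolated).
#'
#' @param path CSV path.
#' @param arena An \code{\link{arena}} describing the recording environment.
#'
#' @return A \code{\link{tracking_data}} object.
#' @export
read_tracking_csv <- function(path, arena) {
  df <- utils::read.csv(path)
  if (all(c("t", "x1", "y1", "x2", "y2") %in% names(df))) {
    tr <- tracking_data(df$t, cbind(df$x1, df$y1), cbind(df$x2, df$y2),
                        arena = arena)
  } else if (all(c("t", "x", "y") %in% names(df))) {
    tr <- tracking_data(df$t, cbind(df$x, df$y), NULL, arena = arena)
  } else {
    stop("tracking CSV must have columns t,x1,y1,x2,y2 or t,x,y")
  }
  if (mean(!tr$valid) > 0.5) {
    warning("more than 50% of tracking frames are invalid")
  }
  tr
}

#' Read spike timestamps from a plain-text/CSV file
#'
#' @param path File with one spike time (seconds) per line, or a CSV with a
#'   \code{t} column.
#' @param t_start,t_end Recording bounds in seconds; default to the span of
#'   the spike times (or 0..max).
#' @return A \code{\link{spike_train}}.
#' @export
read_spike_times <- function(path, t_start = NULL, t_end = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("[a-zA-Z]", first)) {
    times <- utils::read.csv(path)$t
  } else {
    times <- scan(path, quiet = TRUE)
  }
  times <- sort(as.numeric(times))
  if (is.null(t_start)) t_start <- min(0, times)
  if (is.null(t_end)) t_end <- if (length(times)) max(times) else 1
  spike_train(times, t_start, t_end)
}

#' Read a cohort table of recording metadata
#'
#' @param path CSV with columns \code{cell_id, rat_id, arena, duration_s,
#'   n_spikes} and optionally \code{identified, layer_assignment,
#'   shoulder_detected, activity_class}. If \code{activity_class} is absent
#'   it is derived from \code{n_spikes}/\code{duration_s} via
#'   \code{\link{classify_activity}}.
#' @param cfg A \code{\link{run_config}}.
#' @return A data.frame of class \code{cohort_table}.
#' @export
read_cohort_csv <- function(path, cfg = run_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "duration_s", "n_spikes")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns ", paste(need, collapse = ", "))
  }
  if (any(df$duration_s <= 0)) stop("duration_s must be > 0")
  derived <- vapply(seq_len(nrow(df)), function(i) {
    classify_activity_rate(df$n_spikes[i], df$duration_s[i], cfg)
  }, character(1))
  if (!"activity_class" %in% names(df)) {
    df$activity_class <- derived
  } else if (!all(df$activity_class == derived)) {
    stop("activity_class column inconsistent with n_spikes/duration_s for cell(s) ",
         paste(df$cell_id[df$activity_class != derived], collapse = ", "))
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a morphometric feature table
#'
#' Loads a per-cell CSV of the ten primary dendritic features used by the
#' active/silent classifier: total dendritic length, per-order lengths for
#' orders 1-7, number of primary dendrites and number of dendritic endings.
#' A table of measured reconstructions (such as a published per-cell source
#' table) can be supplied here in place of SWC files.
#'
#' @param path CSV with a \code{cell_id} column, a \code{label} column
#'   (\code{active}/\code{silent}) and the ten feature columns
#'   \code{total_length, order1..order7, n_primary, n_endings}.
#' @return A list with \code{X} (numeric matrix, 10 columns), \code{y}
#'   (factor active/silent) and \code{cell_id}.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feat <- c("total_length", paste0("order", 1:7), "n_primary", "n_endings")
  if (!all(c("cell_id", "label", feat) %in% names(df))) {
    stop("feature CSV must have columns cell_id, label, ",
         paste(feat, collapse = ", "))
  }
  X <- as.matrix(df[, feat])
  storage.mode(X) <- "double"
  list(X = X, y = factor(df$label, levels = c("silent", "active")),
       cell_id = df$cell_id)
}

#' Write a structured result report to JSON
#'
#' Serializes any of the pipeline's report objects (shoulder results, spatial
#' reports, classifier reports, ...) together with a configuration echo, the
#' package version and the RNG seed, at full numeric precision so a re-run
#' from the report is reproducible.
#'
#' @param result A (possibly classed) list of results.
#' @param path Output JSON path.
#' @param cfg Optional \code{\link{run_config}} echoed into the report.
#' @param seed Optional RNG seed echoed into the report.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(result, path, cfg = NULL, seed = NULL) {
  bad <- find_unserializable(result)
  if (length(bad)) {
    stop("unserializable field: ", bad[1])
  }
  payload <- list(
    package = "sparsegc",
    version = as.character(utils::packageVersion("sparsegc")),
    seed = seed,
    config = if (!is.null(cfg)) unclass(cfg),
    result = strip_classes(result)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON file written by \code{\link{write_report}}.
#' @return The parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

find_unserializable <- function(x, path = "result") {
  if (is.function(x) || is.environment(x) ||
      (typeof(x) %in% c("externalptr", "S4"))) {
    return(path)
  }
  if (is.list(x)) {
    nms <- names(x)
    out <- character(0)
    for (i in seq_along(x)) {
      sub <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, find_unserializable(x[[i]], paste(path, sub, sep = "$")))
    }
    return(out)
  }
  character(0)
}
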