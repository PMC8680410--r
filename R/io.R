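#' @include AllClasses.R
NULL

#' Read and write release curves as delimited text
#'
#' Two/three-column tab-separated text with a header:
#' `time_days`, `rate` and, when the curve was recorded at non-zero
#' ambient oxygen, `oxygen`.
#'
#' @param curve a [ReleaseCurve-class].
#' @param path file path.
#' @return `writeReleaseCurve` returns `path` invisibly;
#'   `readReleaseCurve` returns a [ReleaseCurve-class].
#' @export
writeReleaseCurve <- function(curve, path) {
  df <- data.frame(time_days = curve@times, rate = curve@rates)
  if (any(curve@oxygen != 0))
    df$oxygen <- rep_len(curve@oxygen, length(curve@times))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeReleaseCurve
#' @export
readReleaseCurve <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  new("ReleaseCurve", times = df$time_days, rates = df$rate,
      oxygen = if ("oxygen" %in% names(df)) df$oxygen else 0,
      noise_sd = 0)
}

#' Read and write bead layouts as delimited text
#'
#' Tab-separated `row`, `col`, `type` with a header; the grid extent
#' and release parameters are carried in comment lines.
#'
#' @param beads a [BeadSet-class].
#' @param path file path.
#' @param p a [ModelParameters-class] used to restore release
#'   constants on read.
#' @return `writeBeadSet` returns `path` invisibly; `readBeadSet` a
#'   [BeadSet-class].
#' @export
writeBeadSet <- function(beads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid %d %d seed %d", beads@grid_nx,
                     beads@grid_ny, beads@placement_seed), con)
  writeLines("row\tcol\ttype", con)
  if (nrow(beads@sites))
    writeLines(sprintf("%d\t%d\t%s", beads@sites[, 1], beads@sites[, 2],
                       beads@bead_type), con)
  invisible(path)
}

#' @rdname writeBeadSet
#' @export
readBeadSet <- function(path, p = defaultParameters()) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# grid ", "", lines[1]), " ")[[1]]
  df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t")
  type <- if (nrow(df)) df$type[1] else "CPO"
  bp <- beadParams(type, p)
  new("BeadSet",
      sites = cbind(row = as.integer(df$row), col = as.integer(df$col)),
      bead_type = type, G_n = bp$G_n, H_n = bp$H_n, hill_h = bp$hill_h,
      tau = bp$tau, placement_seed = as.integer(hdr[4]),
      grid_nx = as.integer(hdr[1]), grid_ny = as.integer(hdr[2]))
}

#' Serialize a vascular network as delimited text
#'
#' Writes `<stem>_agents.tsv` (id, site, role, sprout and the 8
#' intracellular species) and `<stem>_segments.tsv` (edge list with
#' perfusion flags). `writeNetworkGraphML` additionally exports the
#' connectivity in GraphML, a standard graph-exchange text format.
#'
#' @param net a [VascularNetwork-class].
#' @param stem path stem for the two tables.
#' @return the written path(s), invisibly.
#' @export
writeVascularNetwork <- function(net, stem) {
  ag <- data.frame(id = seq_len(nAgents(net)),
                   row = net@sites[, 1], col = net@sites[, 2],
                   role = net@role, sprout_id = net@sprout_id,
                   is_root = seq_len(nAgents(net)) %in% net@boundary_roots)
  ag <- cbind(ag, as.data.frame(net@state))
  pa <- paste0(stem, "_agents.tsv")
  ps <- paste0(stem, "_segments.tsv")
  utils::write.table(ag, pa, sep = "\t", row.names = FALSE, quote = FALSE)
  se <- data.frame(from = net@segments[, 1], to = net@segments[, 2],
                   perfused = net@perfused)
  utils::write.table(se, ps, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(pa, ps))
}

#' @rdname writeVascularNetwork
#' @export
readVascularNetwork <- function(stem, grid_nx, grid_ny) {
  ag <- utils::read.table(paste0(stem, "_agents.tsv"), header = TRUE,
                          sep = "\t")
  se <- utils::read.table(paste0(stem, "_segments.tsv"), header = TRUE,
                          sep = "\t")
  state <- as.matrix(ag[, .STATE_NAMES])
  dimnames(state) <- list(NULL, .STATE_NAMES)
  segs <- if (nrow(se)) cbind(as.integer(se$from), as.integer(se$to))
  else matrix(0L, 0, 2)
  new("VascularNetwork",
      sites = cbind(as.integer(ag$row), as.integer(ag$col)),
      role = as.character(ag$role), state = state,
      sprout_id = as.integer(ag$sprout_id), segments = segs,
      perfused = as.logical(se$perfused),
      boundary_roots = as.integer(ag$id[ag$is_root]),
      grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny))
}

#' @rdname writeVascularNetwork
#' @param path GraphML output path.
#' @export
writeNetworkGraphML <- function(net, path) {
  gr <- igraph::make_graph(t(net@segments), n = nAgents(net),
                           directed = FALSE)
  igraph::V(gr)$row <- net@sites[, 1]
  igraph::V(gr)$col <- net@sites[, 2]
  igraph::V(gr)$role <- net@role
  if (nSegments(net)) igraph::E(gr)$perfused <- net@perfused
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

#' Export a single field as delimited text
#'
#' @param field a numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFieldTable <- function(field, path) {
  utils::write.table(field, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write simulation snapshots as a hierarchical text container
#'
#' A self-describing on-disk layout: `manifest.json` records the
#' scenario, capture times and field names; each captured timepoint
#' owns a subdirectory (`t_<time>/`) holding one tab-separated table
#' per field. The scenario configuration is echoed to `config.txt` for
#' provenance, and the metric table to `metrics.tsv`.
#'
#' @param result a [SimulationResult-class] run with
#'   `keep_snapshots = TRUE` (the final fields are written even
#'   without snapshots).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSnapshots <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snaps <- result@snapshots
  if (!length(snaps))
    snaps <- stats::setNames(list(result@fields),
                             format(result@fields@t))
  fields <- c("oxygen", "vegf", "progenitor", "fibroblast", "fibrous")
  manifest <- list(
    package = "oxybeads",
    grid = c(result@config@grid_nx, result@config@grid_ny),
    dx_mm = result@config@dx,
    seed = result@seed,
    times = as.numeric(names(snaps)),
    fields = fields)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeScenarioConfig(result@config, file.path(dir, "config.txt"))
  utils::write.table(result@metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(snaps)) {
    sub <- file.path(dir, paste0("t_", nm))
    dir.create(sub, showWarnings = FALSE)
    fl <- snaps[[nm]]
    for (f in fields)
      writeFieldTable(slot(fl, if (f == "fibrous") "fibrous" else f),
                      file.path(sub, paste0(f, ".tsv")))
  }
  invisible(dir)
}
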