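#' COLVAR-dialect trajectory files
#'
#' Whitespace-separated text with a `#! FIELDS time <cvs...> metad.bias`
#' header and `#! SET` metadata lines (per-CV periodicity and units,
#' plus optional provenance). Values are written with full double
#' precision, so files round-trip exactly and a second write of a read
#' file is byte-identical.
#'
#' @param traj a [cv_trajectory()].
#' @param path file path.
#' @param provenance optional named character vector written as extra
#'   `#! SET` lines (e.g. generating subcommand and config digest).
#' @return `write_colvar` returns `path` invisibly; `read_colvar` a
#'   [cv_trajectory()].
#' @export
write_colvar <- function(traj, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS time",
                   paste(traj$labels, collapse = " "), "metad.bias"), con)
  for (i in seq_along(traj$labels)) {
    writeLines(sprintf("#! SET periodic_%s %s", traj$labels[i],
                       tolower(traj$periodic[i])), con)
    writeLines(sprintf("#! SET unit_%s %s", traj$labels[i],
                       traj$units[i]), con)
  }
  for (nm in names(provenance))
    writeLines(sprintf("#! SET %s %s", nm, provenance[[nm]]), con)
  if (length(traj$time)) {
    m <- cbind(traj$time, traj$values, traj$bias)
    writeLines(apply(m, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

parse_dialect_header <- function(lines, what) {
  if (length(lines) == 0L || !startsWith(lines[1], "#! FIELDS"))
    stop_parse(what, " parse error at line 1: missing '#! FIELDS' header")
  fields <- strsplit(sub("^#! FIELDS +", "", lines[1]), " +")[[1]]
  sets <- list()
  i <- 2L
  while (i <= length(lines) && startsWith(lines[i], "#!")) {
    if (!startsWith(lines[i], "#! SET "))
      stop_parse(what, " parse error at line ", i, ": malformed header line")
    tok <- strsplit(sub("^#! SET +", "", lines[i]), " +")[[1]]
    if (length(tok) < 2L)
      stop_parse(what, " parse error at line ", i, ": malformed SET line")
    sets[[tok[1]]] <- paste(tok[-1], collapse = " ")
    i <- i + 1L
  }
  list(fields = fields, sets = sets, first_data = i)
}

read_dialect_rows <- function(lines, first, ncol, what) {
  if (first > length(lines))
    return(matrix(numeric(0), 0L, ncol))
  rows <- lines[first:length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) == 0L)
    return(matrix(numeric(0), 0L, ncol))
  out <- matrix(0, length(rows), ncol)
  for (r in seq_along(rows)) {
    tok <- strsplit(trimws(rows[r]), "[ \t]+")[[1]]
    if (length(tok) != ncol)
      stop_parse(what, " parse error at line ", first + r - 1L, ": expected ",
                 ncol, " columns, found ", length(tok))
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v) && !all(tok[is.na(v)] == "NA"))
      stop_parse(what, " parse error at line ", first + r - 1L,
                 ": non-numeric value")
    out[r, ] <- v
  }
  out
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  hd <- parse_dialect_header(lines, "COLVAR")
  nf <- length(hd$fields)
  if (nf < 3L || hd$fields[1] != "time" || hd$fields[nf] != "metad.bias")
    stop_parse("COLVAR parse error at line 1: fields must be time, CVs, ",
               "metad.bias")
  labels <- hd$fields[-c(1L, nf)]
  m <- read_dialect_rows(lines, hd$first_data, nf, "COLVAR")
  if (nrow(m) > 1L && any(diff(m[, 1]) < 0)) {
    bad <- which(diff(m[, 1]) < 0)[1]
    stop_parse("COLVAR parse error at line ",
               hd$first_data + bad, ": times not monotonically increasing")
  }
  periodic <- vapply(labels, function(l)
    identical(hd$sets[[paste0("periodic_", l)]], "true"), logical(1))
  units <- vapply(labels, function(l)
    hd$sets[[paste0("unit_", l)]] %||% "A", character(1))
  vals <- m[, 1L + seq_along(labels), drop = FALSE]
  colnames(vals) <- labels
  cv_trajectory(m[, 1], vals, m[, nf], units = unname(units),
                periodic = unname(periodic))
}

#' HILLS-dialect bias files
#'
#' One line per deposited hill — time, centers, widths, height and the
#' bias factor \eqn{(T+\Delta T)/T} — under a `#! FIELDS` header whose
#' `#! SET` lines carry per-CV periodicity/units, the grid
#' specification and the well-tempered parameters, so a read file
#' reconstructs the full bias (grid cache included) exactly.
#'
#' @param bias a [new_bias_state()].
#' @param path file path.
#' @param provenance optional named character vector of extra `#! SET`
#'   lines.
#' @return `write_hills` returns `path` invisibly; `read_hills` a
#'   [new_bias_state()].
#' @export
write_hills <- function(bias, path, provenance = NULL) {
  d <- bias$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS time",
                   paste(paste0("center_", bias$labels), collapse = " "),
                   paste(paste0("sigma_", bias$labels), collapse = " "),
                   "height biasf"), con)
  for (i in seq_len(d)) {
    l <- bias$labels[i]
    writeLines(sprintf("#! SET periodic_%s %s", l,
                       tolower(bias$periodic[i])), con)
    writeLines(sprintf("#! SET unit_%s %s", l, bias$units[i]), con)
    writeLines(sprintf("#! SET grid_min_%s %.17g", l, bias$gmin[i]), con)
    writeLines(sprintf("#! SET grid_max_%s %.17g", l, bias$gmax[i]), con)
    writeLines(sprintf("#! SET grid_bins_%s %d", l, bias$nbins[i]), con)
  }
  writeLines(sprintf("#! SET temperature %.17g", bias$temperature), con)
  writeLines(sprintf("#! SET delta_t %.17g", bias$delta_t), con)
  writeLines(sprintf("#! SET w0 %.17g", bias$w0), con)
  writeLines(sprintf("#! SET tau %.17g", bias$tau), con)
  for (nm in names(provenance))
    writeLines(sprintf("#! SET %s %s", nm, provenance[[nm]]), con)
  biasf <- (bias$temperature + bias$delta_t) / bias$temperature
  H <- hills_matrix(bias)
  if (nrow(H)) {
    m <- cbind(H, biasf)
    writeLines(apply(m, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  hd <- parse_dialect_header(lines, "HILLS")
  fields <- hd$fields
  if (fields[1] != "time" || fields[length(fields)] != "biasf" ||
      fields[length(fields) - 1L] != "height")
    stop_parse("HILLS parse error at line 1: fields must be time, centers, ",
               "sigmas, height, biasf")
  d <- (length(fields) - 3L) / 2L
  if (d != round(d) || d < 1L)
    stop_parse("HILLS parse error at line 1: inconsistent field count")
  labels <- sub("^center_", "", fields[1L + seq_len(d)])
  sets <- hd$sets
  getnum <- function(key) {
    v <- sets[[key]]
    if (is.null(v)) stop_parse("HILLS header missing '", key, "'")
    as.numeric(v)
  }
  params <- wt_params(temperature = getnum("temperature"),
                      delta_t = getnum("delta_t"), w0 = getnum("w0"),
                      tau = getnum("tau"),
                      grid_min = vapply(labels, function(l)
                        getnum(paste0("grid_min_", l)), numeric(1)),
                      grid_max = vapply(labels, function(l)
                        getnum(paste0("grid_max_", l)), numeric(1)),
                      grid_bins = vapply(labels, function(l)
                        as.integer(getnum(paste0("grid_bins_", l))),
                        integer(1)))
  periodic <- vapply(labels, function(l)
    identical(sets[[paste0("periodic_", l)]], "true"), logical(1))
  units <- vapply(labels, function(l)
    sets[[paste0("unit_", l)]] %||% "A", character(1))
  m <- read_dialect_rows(lines, hd$first_data, length(fields), "HILLS")
  bias <- new_bias_state(params, labels = labels, units = unname(units),
                         periodic = unname(periodic))
  if (nrow(m)) {
    # widths recorded per hill; the state's nominal widths follow the file
    bias$widths <- m[1, 1L + d + seq_len(d)]
    nh <- nrow(m)
    need <- 2L^ceiling(log2(max(nh, 256L)))
    hills <- matrix(0, need, 2L * d + 2L)
    colnames(hills) <- colnames(bias$hills)
    hills[seq_len(nh), ] <- m[, seq_len(2L * d + 2L)]
    bias$hills <- hills
    bias$n_hills <- nh
    for (k in seq_len(nh))
      add_hill_to_grid(bias, m[k, 1L + seq_len(d)], m[k, 2L * d + 2L],
                       sigma = m[k, 1L + d + seq_len(d)])
  }
  bias
}

#' FES grid files
#'
#' One row per bin — bin-center coordinates, free energy (`NA` for
#' unvisited bins), visited flag and occupancy count — with the full
#' bin-edge vectors carried in the header so the grid reconstructs
#' exactly.
#'
#' @param fes a [fes_grid()].
#' @param path file path.
#' @param provenance optional named character vector of extra `#! SET`
#'   lines.
#' @return `write_fes` returns `path` invisibly; `read_fes` a
#'   [fes_grid()].
#' @export
write_fes <- function(fes, path, provenance = NULL) {
  d <- fes$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fes$labels, collapse = " "),
                   "free_energy visited count"), con)
  for (i in seq_len(d)) {
    writeLines(sprintf("#! SET unit_%s %s", fes$labels[i], fes$units[i]), con)
    writeLines(paste("#! SET edges_", fes$labels[i], " ",
                     paste(sprintf("%.17g", fes$breaks[[i]]), collapse = " "),
                     sep = ""), con)
  }
  writeLines(sprintf("#! SET temperature %.17g", fes$temperature), con)
  for (nm in names(provenance))
    writeLines(sprintf("#! SET %s %s", nm, provenance[[nm]]), con)
  ctr <- fes_centers(fes)
  counts <- fes$counts %||% (fes$visited * 0L)
  vals <- as.numeric(fes$values)
  vis <- as.integer(fes$visited)
  cnt <- as.integer(counts)
  if (d == 1L) {
    coords <- matrix(ctr[[1]], ncol = 1)
  } else {
    n1 <- length(ctr[[1]]); n2 <- length(ctr[[2]])
    coords <- cbind(rep(ctr[[1]], times = n2), rep(ctr[[2]], each = n1))
  }
  lines_out <- vapply(seq_along(vals), function(i) {
    fv <- if (is.finite(vals[i])) sprintf("%.17g", vals[i]) else "NA"
    paste(paste(sprintf("%.17g", coords[i, ]), collapse = " "), fv,
          vis[i], cnt[i])
  }, character(1))
  writeLines(lines_out, con)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  lines <- readLines(path)
  hd <- parse_dialect_header(lines, "FES")
  fields <- hd$fields
  d <- length(fields) - 3L
  if (d < 1L || d > 2L ||
      !identical(fields[d + 1:3], c("free_energy", "visited", "count")))
    stop_parse("FES parse error at line 1: unexpected fields")
  labels <- fields[seq_len(d)]
  breaks <- lapply(labels, function(l) {
    v <- hd$sets[[paste0("edges_", l)]]
    if (is.null(v)) stop_parse("FES header missing edges for ", l)
    as.numeric(strsplit(v, " +")[[1]])
  })
  units <- vapply(labels, function(l)
    hd$sets[[paste0("unit_", l)]] %||% "A", character(1))
  temperature <- as.numeric(hd$sets[["temperature"]] %||% "300")
  m <- read_dialect_rows(lines, hd$first_data, length(fields), "FES")
  nb <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  if (nrow(m) != prod(nb))
    stop_parse("FES parse error: ", nrow(m), " rows for ", prod(nb), " bins")
  vals <- m[, d + 1L]
  counts <- as.integer(m[, d + 3L])
  if (d == 2L) {
    vals <- matrix(vals, nb[1], nb[2])
    counts <- matrix(counts, nb[1], nb[2])
  }
  fes_grid(breaks, vals, labels = labels, units = unname(units),
           temperature = temperature, counts = counts, anchor = FALSE)
}

#' Write a basin table as tab-separated text
#'
#' @param basins list of basins from [find_minima()].
#' @param fes the grid they belong to.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_basin_table <- function(basins, fes, path) {
  rows <- lapply(basins, function(b) {
    loc <- rep(NA_real_, 2)
    loc[seq_along(b$location)] <- b$location
    data.frame(basin = b$label, cv1 = loc[1],
               cv2 = if (fes$dim == 2L) loc[2] else NA_real_,
               f_min = b$fmin, n_bins = length(b$members), prob = b$prob)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
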