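# Montages, fiducials, digitization sessions and persistence.
#
# A montage is the ordered, labeled electrode set of a cap (e.g. BioSemi
# 128-channel A1..D32), optionally with template positions.  A session
# collects repeated fiducial measurements (aggregated by averaging, with a
# max-pairwise-distance spread check), electrode measurements keyed by
# montage label, and arbitrary head-shape points.

FIDUCIAL_SPREAD_WARN_MM <- 3   # repeated-fiducial consistency warning
SESSION_SCHEMA_VERSION <- 1L

# labels commonly used for fiducial rows in montage files
KNOWN_FIDUCIAL_LABELS <- c("nasion" = "nasion", "nas" = "nasion",
                           "nz" = "nasion", "fidnz" = "nasion",
                           "lpa" = "lpa", "fidt9" = "lpa",
                           "rpa" = "rpa", "fidt10" = "rpa")

#' Construct a montage
#'
#' @param labels character vector of unique electrode labels, in cap order.
#' @param template optional matrix of template positions (mm) with rownames
#'   a subset of `labels`.
#' @return Object of class `montage`.
#' @export
montage <- function(labels, template = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop(sprintf("montage: duplicate labels: %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
         call. = FALSE)
  if (!length(labels)) stop("montage: no electrode labels", call. = FALSE)
  if (!is.null(template)) {
    template <- as.matrix(template)
    stopifnot(ncol(template) == 3L)
    if (!all(rownames(template) %in% labels))
      stop("montage: template positions for unknown labels", call. = FALSE)
  }
  structure(list(labels = labels, template = template), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("montage: %d electrodes (%s ... %s)%s\n", length(x$labels),
              x$labels[1], x$labels[length(x$labels)],
              if (is.null(x$template)) "" else ", with template positions"))
  invisible(x)
}

#' BioSemi-style radial label sequence
#'
#' Labels A1..A32, B1..B32, ... covering `n` electrodes in banks of 32.
#' @param n number of electrodes (default 128).
#' @export
biosemi_labels <- function(n = 128L) {
  banks <- LETTERS[seq_len(ceiling(n / 32))]
  paste0(rep(banks, each = 32), rep(1:32, length(banks)))[seq_len(n)]
}

#' Read a montage file
#'
#' Supported dialects: `.sfp` (whitespace separated: `label x y z`, assumed
#' mm), `.elc` (ASA-style, with `UnitPosition`, `Positions` and `Labels`
#' sections), and plain CSV (`label,x,y,z`, optional header).  Rows whose
#' label is a recognized fiducial name (nasion/nz/fidnz, lpa/fidt9,
#' rpa/fidt10) are routed to the fiducial template rather than the montage.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sfp"`, `"elc"` or `"csv"`.
#' @return list with `montage` (a `montage`) and `fiducials` (named list of
#'   length-3 template positions, possibly empty).
#' @export
read_montage <- function(path, format = c("auto", "sfp", "elc", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sfp = "sfp", elc = "elc", csv = "csv",
                     stop(sprintf("cannot infer montage format from '.%s'", ext),
                          call. = FALSE))
  }
  rows <- switch(format,
                 sfp = parse_sfp(path),
                 csv = parse_montage_csv(path),
                 elc = parse_elc(path))
  if (!nrow(rows)) stop(sprintf("montage format error: %s is empty", path),
                        call. = FALSE)
  is_fid <- tolower(rows$label) %in% names(KNOWN_FIDUCIAL_LABELS)
  fids <- list()
  for (i in which(is_fid)) {
    nm <- KNOWN_FIDUCIAL_LABELS[[tolower(rows$label[i])]]
    fids[[nm]] <- c(rows$x[i], rows$y[i], rows$z[i])
  }
  el <- rows[!is_fid, , drop = FALSE]
  if (!nrow(el)) stop("montage format error: no electrode rows", call. = FALSE)
  tmpl <- NULL
  if (all(is.finite(el$x))) {
    tmpl <- as.matrix(el[, c("x", "y", "z")])
    rownames(tmpl) <- el$label
  }
  list(montage = montage(el$label, template = tmpl), fiducials = fids)
}

parse_sfp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  out <- data.frame(label = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), stringsAsFactors = FALSE)
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) != 4L)
      stop(sprintf("%s line %d: expected 'label x y z', got %d fields",
                   path, i, length(f)), call. = FALSE)
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(xyz)))
      stop(sprintf("%s line %d: non-numeric coordinates", path, i),
           call. = FALSE)
    out[nrow(out) + 1L, ] <- list(f[1], xyz[1], xyz[2], xyz[3])
  }
  out
}

parse_montage_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(data.frame(label = character(0), x = numeric(0),
                                        y = numeric(0), z = numeric(0)))
  first <- strsplit(lines[1], ",")[[1]]
  has_header <- length(first) >= 1 &&
    is.na(suppressWarnings(as.numeric(trimws(first[min(2, length(first))]))))
  start <- if (has_header) 2L else 1L
  out <- data.frame(label = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), stringsAsFactors = FALSE)
  for (i in seq(start, length(lines))) {
    f <- trimws(strsplit(lines[i], ",")[[1]])
    if (length(f) == 1L && nzchar(f)) {
      out[nrow(out) + 1L, ] <- list(f[1], NA_real_, NA_real_, NA_real_)
      next
    }
    if (length(f) != 4L)
      stop(sprintf("%s line %d: expected 'label,x,y,z'", path, i), call. = FALSE)
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(xyz)))
      stop(sprintf("%s line %d: non-numeric coordinates", path, i), call. = FALSE)
    out[nrow(out) + 1L, ] <- list(f[1], xyz[1], xyz[2], xyz[3])
  }
  out
}

# empty-safe ascending seq
seq2 <- function(from, to) if (to < from) integer(0) else seq(from, to)

parse_elc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lt <- trimws(lines)
  unit <- 1  # mm
  u <- grep("^UnitPosition", lt, value = TRUE)
  if (length(u)) {
    uv <- tolower(trimws(sub("^UnitPosition", "", u[1])))
    unit <- switch(uv, mm = 1, cm = 10, m = 1000,
                   stop(sprintf("%s: unknown UnitPosition '%s'", path, uv),
                        call. = FALSE))
  }
  pstart <- grep("^Positions", lt)
  lstart <- grep("^Labels", lt)
  if (!length(pstart) || !length(lstart))
    stop(sprintf("%s: missing Positions/Labels section", path), call. = FALSE)
  # section content runs until the next section keyword or EOF
  section_starts <- sort(c(grep("^(Positions|Labels|NumberPositions|UnitPosition|ReferenceLabel|NumberHeadShapePoints|HeadShapePoints)",
                               lt), length(lt) + 1L))
  sec_end <- function(start) min(section_starts[section_starts > start]) - 1L
  pos_lines <- lt[seq2(pstart[1] + 1L, sec_end(pstart[1]))]
  lab_lines <- lt[seq2(lstart[1] + 1L, sec_end(lstart[1]))]
  pos_lines <- pos_lines[nzchar(pos_lines)]
  labels <- unlist(strsplit(paste(lab_lines, collapse = " "), "[[:space:]]+"))
  labels <- labels[nzchar(labels)]
  xyz <- t(vapply(pos_lines, function(l) {
    # tolerate "label: x y z" and bare "x y z" rows
    l <- sub("^[^:]*:", "", l)
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
    if (length(v) != 3L || any(is.na(v)))
      stop(sprintf("%s: malformed position row '%s'", path, l), call. = FALSE)
    v
  }, numeric(3)))
  if (length(labels) != nrow(xyz))
    stop(sprintf("%s: %d labels but %d positions", path, length(labels),
                 nrow(xyz)), call. = FALSE)
  data.frame(label = labels, x = xyz[, 1] * unit, y = xyz[, 2] * unit,
             z = xyz[, 3] * unit, stringsAsFactors = FALSE)
}

## ---- fiducials ------------------------------------------------------------

#' Aggregate repeated fiducial measurements
#'
#' Each fiducial's aggregate position is the mean of its repeats; the spread
#' metric is the maximum pairwise distance among repeats.  Spreads above the
#' warning threshold are flagged.
#'
#' @param fiducials named list; each element a matrix of repeats (k x 3, mm)
#'   or a single length-3 vector.
#' @param warn_mm spread warning threshold (default 3 mm).
#' @return Object of class `fiducial_set`: named list with per-fiducial
#'   `repeats`, `aggregate`, `spread_mm`, `flagged`.
#' @export
aggregate_fiducials <- function(fiducials, warn_mm = FIDUCIAL_SPREAD_WARN_MM) {
  stopifnot(is.list(fiducials), length(fiducials) >= 1L,
            !is.null(names(fiducials)))
  out <- lapply(fiducials, function(reps) {
    if (!is.matrix(reps)) reps <- matrix(as.numeric(reps), ncol = 3)
    stopifnot(ncol(reps) == 3L, nrow(reps) >= 1L)
    spread <- if (nrow(reps) > 1L) max(stats::dist(reps)) else 0
    list(repeats = reps, aggregate = colMeans(reps), spread_mm = spread,
         flagged = spread > warn_mm)
  })
  structure(out, class = "fiducial_set")
}

fiducial_positions <- function(fset) {
  stopifnot(inherits(fset, "fiducial_set"))
  do.call(rbind, lapply(fset, function(f) f$aggregate))
}

## ---- sessions -------------------------------------------------------------

#' Create an empty digitization session
#'
#' @param montage A `montage`.
#' @param fiducial_names fiducial names to measure (default nasion, lpa,
#'   rpa; arbitrary fiducial sets are allowed).
#' @param tracker_ids optional head-tracker device ids (0-2).
#' @param provenance free-form list (system name, endpoint, timestamps ...).
#' @return Object of class `digitization_session`.
#' @export
digitization_session <- function(montage,
                                 fiducial_names = c("nasion", "lpa", "rpa"),
                                 tracker_ids = NULL, provenance = list()) {
  stopifnot(inherits(montage, "montage"))
  provenance$created <- provenance$created %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  structure(list(montage = montage,
                 fiducial_names = as.character(fiducial_names),
                 fiducial_repeats = stats::setNames(
                   vector("list", length(fiducial_names)), fiducial_names),
                 electrodes = list(),     # label -> measurement_sample-like list
                 rejected = character(0),
                 headshape = list(),
                 tracker_ids = tracker_ids,
                 provenance = provenance,
                 complete = FALSE),
            class = "digitization_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.digitization_session <- function(x, ...) {
  nf <- sum(!vapply(x$fiducial_repeats, is.null, logical(1)))
  cat(sprintf(paste0("digitization_session: %d/%d fiducials, %d/%d electrodes",
                     " (%d rejected), %d headshape points\n"),
              nf, length(x$fiducial_names), length(x$electrodes),
              length(x$montage$labels), length(x$rejected),
              length(x$headshape)))
  invisible(x)
}

#' Add a measurement to a session
#'
#' Routes by role: fiducial measurements accumulate as repeats, electrode
#' measurements are keyed by montage label (an unknown label is an error),
#' headshape points are appended.
#'
#' @param session A `digitization_session`.
#' @param m A `measurement_sample`.
#' @return The updated session.
#' @export
session_add_measurement <- function(session, m) {
  stopifnot(inherits(session, "digitization_session"),
            inherits(m, "measurement_sample"))
  if (m$role == "fiducial") {
    if (!(m$label %in% session$fiducial_names))
      stop(sprintf("unknown fiducial '%s'", m$label), call. = FALSE)
    session$fiducial_repeats[[m$label]] <-
      rbind(session$fiducial_repeats[[m$label]], m$position)
  } else if (m$role == "electrode") {
    if (!(m$label %in% session$montage$labels))
      stop(sprintf("unknown electrode label '%s'", m$label), call. = FALSE)
    session$electrodes[[m$label]] <-
      list(position = m$position, frame = m$frame, valid = m$valid,
           stability_mm = m$stability_mm, t = m$t)
  } else if (m$role == "headshape") {
    session$headshape[[length(session$headshape) + 1L]] <-
      list(tag = m$label, position = m$position, t = m$t)
  } else stop(sprintf("unknown role '%s'", m$role), call. = FALSE)
  session
}

#' Aggregated fiducials of a session
#' @param session A `digitization_session`.
#' @param warn_mm spread warning threshold (mm).
#' @return A `fiducial_set` (see [aggregate_fiducials()]).
#' @export
session_fiducials <- function(session, warn_mm = FIDUCIAL_SPREAD_WARN_MM) {
  reps <- Filter(Negate(is.null), session$fiducial_repeats)
  if (!length(reps)) stop("session has no fiducial measurements", call. = FALSE)
  aggregate_fiducials(reps, warn_mm = warn_mm)
}

#' Next measurement target of a session
#'
#' Fiducials come first (in declared order, `fiducial_repeats` times each),
#' then electrodes in montage order; measured targets are skipped.  Returns
#' the sentinel `"done"` when nothing is pending.
#'
#' @param session A `digitization_session`.
#' @param fiducial_repeats repeats required per fiducial (default 1).
#' @return A target label, or `"done"`.
#' @export
next_target <- function(session, fiducial_repeats = 1L) {
  for (nm in session$fiducial_names) {
    k <- nrow(session$fiducial_repeats[[nm]] %||% matrix(nrow = 0, ncol = 3))
    if (k < fiducial_repeats) return(nm)
  }
  for (lab in session$montage$labels)
    if (is.null(session$electrodes[[lab]])) return(lab)
  "done"
}

#' Append fiducial re-measurements as head-shape points
#'
#' After the main sequence, each fiducial may be re-measured as a tagged
#' head-shape point; the aggregated fiducials are left untouched.  A
#' re-measurement farther than `warn_mm` from the aggregate raises a
#' consistency warning.
#'
#' @param session A `digitization_session` with measured fiducials.
#' @param remeasurements named list: fiducial name -> k x 3 matrix (or
#'   length-3 vector) of re-measured positions (mm).
#' @param warn_mm consistency threshold (default 3 mm).
#' @return The updated session; each appended point carries the fiducial tag
#'   and a `consistent` flag.
#' @export
add_headshape_refiducials <- function(session, remeasurements,
                                      warn_mm = FIDUCIAL_SPREAD_WARN_MM) {
  stopifnot(inherits(session, "digitization_session"))
  if (!length(remeasurements)) return(session)
  fids <- session_fiducials(session)
  for (nm in names(remeasurements)) {
    if (!(nm %in% names(fids)))
      stop(sprintf("fiducial '%s' was never measured", nm), call. = FALSE)
    reps <- remeasurements[[nm]]
    if (!is.matrix(reps)) reps <- matrix(as.numeric(reps), ncol = 3)
    for (i in seq_len(nrow(reps))) {
      d <- sqrt(sum((reps[i, ] - fids[[nm]]$aggregate)^2))
      if (d > warn_mm)
        warning(sprintf(
          "headshape re-measurement of '%s' is %.1f mm from its aggregate (> %.1f mm)",
          nm, d, warn_mm), call. = FALSE)
      session$headshape[[length(session$headshape) + 1L]] <-
        list(tag = nm, position = reps[i, ], t = NA_real_, consistent = d <= warn_mm)
    }
  }
  session
}

#' Positions of the usable electrodes of a session
#'
#' Rejected electrodes and electrodes whose measurement failed the
#' stability gate are excluded by default.
#' @param session A `digitization_session`.
#' @param include_rejected keep rejected and gate-invalid electrodes too?
#' @return matrix with one row per electrode, rownames = labels.
#' @export
electrode_positions <- function(session, include_rejected = FALSE) {
  labs <- names(session$electrodes)
  if (!include_rejected) {
    labs <- setdiff(labs, session$rejected)
    labs <- labs[vapply(labs, function(l)
      isTRUE(session$electrodes[[l]]$valid), logical(1))]
  }
  if (!length(labs)) return(matrix(numeric(0), 0, 3))
  out <- do.call(rbind, lapply(labs, function(l) session$electrodes[[l]]$position))
  rownames(out) <- labs
  out
}

## ---- persistence ----------------------------------------------------------

#' Save / load a digitization session as JSON
#'
#' The session file declares its schema version and unit ("mm") and stores
#' positions at 17 significant digits so that save-then-load round-trips
#' positions to better than 1e-12 mm and every flag exactly.
#'
#' @param session A `digitization_session`.
#' @param path file path.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "digitization_session"))
  x <- list(schema_version = SESSION_SCHEMA_VERSION, units = "mm",
            montage = list(labels = session$montage$labels,
                           template = if (is.null(session$montage$template)) NULL
                                      else list(labels = rownames(session$montage$template),
                                                xyz = unname(session$montage$template))),
            fiducial_names = session$fiducial_names,
            fiducial_repeats = lapply(session$fiducial_repeats,
                                      function(m) if (is.null(m)) NULL else unname(m)),
            electrodes = session$electrodes,
            rejected = session$rejected,
            headshape = session$headshape,
            tracker_ids = session$tracker_ids,
            provenance = session$provenance,
            complete = session$complete)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", always_decimal = TRUE)
  invisible(path)
}

#' @rdname save_session
#' @return `load_session`: the restored `digitization_session`.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  if (is.null(x$schema_version) || x$schema_version > SESSION_SCHEMA_VERSION)
    stop("unsupported session schema", call. = FALSE)
  if (!identical(x$units, "mm"))
    stop(sprintf("session units '%s' not supported (expect mm)", x$units),
         call. = FALSE)
  tmpl <- NULL
  if (!is.null(x$montage$template)) {
    tmpl <- do.call(rbind, lapply(x$montage$template$xyz, as.numeric))
    rownames(tmpl) <- unlist(x$montage$template$labels)
  }
  s <- digitization_session(
    montage(unlist(x$montage$labels), template = tmpl),
    fiducial_names = unlist(x$fiducial_names),
    tracker_ids = if (length(x$tracker_ids)) unlist(x$tracker_ids) else NULL,
    provenance = x$provenance)
  s$fiducial_repeats <- lapply(x$fiducial_repeats, function(m) {
    if (is.null(m)) NULL else do.call(rbind, lapply(m, as.numeric))
  })
  names(s$fiducial_repeats) <- names(x$fiducial_repeats)
  s$electrodes <- lapply(x$electrodes, function(e) {
    e$position <- as.numeric(unlist(e$position)); e
  })
  s$rejected <- as.character(unlist(x$rejected))
  s$headshape <- lapply(x$headshape, function(h) {
    h$position <- as.numeric(unlist(h$position)); h
  })
  s$complete <- isTRUE(x$complete)
  s
}

#' Export session electrodes
#'
#' `export_electrodes_csv` writes `label,x,y,z` rows; `export_sfp` writes
#' fiducials (as `fidnz`, `fidt9`, `fidt10` when named nasion/lpa/rpa) then
#' electrodes in `.sfp` layout.  Rejected electrodes are excluded by
#' default.
#'
#' @param session A `digitization_session`.
#' @param path output path.
#' @param include_rejected include rejected electrodes?
#' @export
export_electrodes_csv <- function(session, path, include_rejected = FALSE) {
  pos <- electrode_positions(session, include_rejected)
  df <- data.frame(label = rownames(pos), x = pos[, 1], y = pos[, 2],
                   z = pos[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_electrodes_csv
#' @export
export_sfp <- function(session, path, include_rejected = FALSE) {
  sfp_fid_names <- c(nasion = "fidnz", lpa = "fidt9", rpa = "fidt10")
  lines <- character(0)
  fids <- tryCatch(session_fiducials(session), error = function(e) NULL)
  if (!is.null(fids)) {
    for (nm in names(fids)) {
      out_nm <- if (nm %in% names(sfp_fid_names)) sfp_fid_names[[nm]] else nm
      p <- fids[[nm]]$aggregate
      lines <- c(lines, sprintf("%s\t%.6f\t%.6f\t%.6f", out_nm, p[1], p[2], p[3]))
    }
  }
  pos <- electrode_positions(session, include_rejected)
  for (i in seq_len(nrow(pos)))
    lines <- c(lines, sprintf("%s\t%.6f\t%.6f\t%.6f", rownames(pos)[i],
                              pos[i, 1], pos[i, 2], pos[i, 3]))
  writeLines(lines, path)
  invisible(path)
}

## ---- meshes ---------------------------------------------------------------

#' Read a triangle surface mesh (STL or OFF)
#'
#' Minimal readers for downstream consumers (visualization, co-registration
#' contexts): ASCII and binary STL, and ASCII OFF.  The mesh is validated to
#' have finite vertices and a non-degenerate bounding box; no rendering.
#'
#' @param path file path (`.stl` or `.off`).
#' @return list with `vertices` (n x 3), `faces` (m x 3, 1-based) and `bbox`
#'   (2 x 3 min/max).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext, stl = read_stl(path), off = read_off(path),
                 stop(sprintf("unsupported mesh format '.%s' (use .stl or .off)",
                              ext), call. = FALSE))
  if (!all(is.finite(mesh$vertices)))
    stop("mesh has non-finite vertices", call. = FALSE)
  bbox <- rbind(min = apply(mesh$vertices, 2, min),
                max = apply(mesh$vertices, 2, max))
  if (any(bbox["max", ] - bbox["min", ] <= 0))
    stop("degenerate mesh bounding box", call. = FALSE)
  mesh$bbox <- bbox
  mesh
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head), "solid")
  if (is_ascii) {
    lines <- trimws(readLines(path, warn = FALSE))
    vlines <- grep("^vertex[[:space:]]", lines, value = TRUE)
    if (!length(vlines) || length(vlines) %% 3 != 0)
      stop(sprintf("%s: malformed ASCII STL", path), call. = FALSE)
    verts <- t(vapply(vlines, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "[[:space:]]+")[[1]][2:4]))
      if (any(is.na(v))) stop(sprintf("%s: bad vertex line", path), call. = FALSE)
      v
    }, numeric(3)))
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", n = 80)
    ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    verts <- matrix(0, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", n = 2)
    }
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  list(vertices = unname(verts), faces = faces)
}

read_off <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!identical(toupper(lines[1]), "OFF"))
    stop(sprintf("%s: missing OFF header", path), call. = FALSE)
  counts <- as.numeric(strsplit(lines[2], "[[:space:]]+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf)
    stop(sprintf("%s: truncated OFF file", path), call. = FALSE)
  verts <- t(vapply(lines[3:(2 + nv)], function(l) {
    as.numeric(strsplit(l, "[[:space:]]+")[[1]][1:3])
  }, numeric(3)))
  faces <- t(vapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    v <- as.numeric(strsplit(l, "[[:space:]]+")[[1]])
    if (v[1] != 3) stop(sprintf("%s: only triangle faces supported", path),
                        call. = FALSE)
    v[2:4] + 1
  }, numeric(3)))
  list(vertices = unname(verts), faces = unname(faces))
}
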