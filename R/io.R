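#' Write a bead system (or trajectory frames) as extended XYZ
#'
#' One block per frame: bead count, a comment line carrying the frame time
#' and box length, then per-bead lines `type x y z nx ny nz np_id`
#' (orientation columns are 0 and `np_id` is 0 for network beads).
#' Coordinates are written at full double precision.
#'
#' @param x A `bead_system` or `md_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt_frame <- function(time, pos, nrm, type, npid, box) {
    writeLines(as.character(nrow(pos)), con)
    writeLines(sprintf("time=%.17g box=%.17g", time, box), con)
    npid <- ifelse(is.na(npid), 0L, npid)
    nrm[is.na(nrm)] <- 0
    writeLines(sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g %d",
                       type, pos[, 1], pos[, 2], pos[, 3],
                       nrm[, 1], nrm[, 2], nrm[, 3], npid), con)
  }
  if (inherits(x, "bead_system")) {
    fmt_frame(0, x$positions, x$normals, x$bead_type, x$np_id, x$box_length)
  } else if (inherits(x, "md_trajectory")) {
    N <- dim(x$wrapped)[2]
    nrm_full <- matrix(NA_real_, N, 3)
    for (f in seq_along(x$times)) {
      nrm_full[x$np_bead_index, ] <- x$normals[f, , ]
      fmt_frame(x$times[f], x$wrapped[f, , ], nrm_full, x$bead_type,
                x$np_id, x$box_length)
    }
  } else stop("write_xyz handles bead_system or md_trajectory objects")
  invisible(path)
}

#' Read extended-XYZ frames written by [write_xyz()]
#'
#' @param path Input file.
#' @return A list of frames; each frame has `time`, `box_length`,
#'   `positions`, `normals`, `bead_type`, `np_id`. Malformed input produces
#'   a line-numbered diagnostic.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  fno <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("line %d: expected a bead count (frame %d)", i, fno + 1))
    n <- as.integer(lines[i])
    fno <- fno + 1L
    if (i + 1L > length(lines))
      stop(sprintf("line %d: truncated frame %d (missing comment line)",
                   i + 1L, fno))
    hdr <- lines[i + 1L]
    time <- as.numeric(sub(".*time=([-0-9.eE+]+).*", "\\1", hdr))
    box <- as.numeric(sub(".*box=([-0-9.eE+]+).*", "\\1", hdr))
    if (i + 1L + n > length(lines))
      stop(sprintf("line %d: truncated frame %d (expected %d bead lines)",
                   length(lines) + 1L, fno, n))
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(body, "\\s+")
    bad <- which(lengths(parts) != 8)
    if (length(bad) > 0)
      stop(sprintf("line %d: malformed bead record in frame %d",
                   i + 1L + bad[1], fno))
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:8))), n, 7,
                byrow = TRUE)
    type <- vapply(parts, `[`, "", 1)
    npid <- as.integer(m[, 7])
    nrm <- m[, 4:6, drop = FALSE]
    nrm[npid == 0L, ] <- NA_real_
    frames[[fno]] <- list(time = time, box_length = box,
                          positions = m[, 1:3, drop = FALSE],
                          normals = nrm, bead_type = type,
                          np_id = ifelse(npid == 0L, NA_integer_, npid))
    i <- i + 2L + n
  }
  frames
}

#' Write tidy observable tables as CSV
#'
#' @param x A tibble (e.g. a `contact_series`, `shape_series`, tidy MSD).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Serialize an experiment configuration to YAML
#'
#' @param config An [experiment_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' @param path Input file.
#' @return An `experiment_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(experiment_config, x)
}
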