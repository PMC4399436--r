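#' Write a volume grid as NRRD
#'
#' Single-file NRRD with explicit spacing (`space directions`) and origin
#' (`space origin`); `raw` encoding stores little-endian float32, `ascii`
#' stores whitespace-separated numbers (text-only, useful for small
#' fixtures).
#'
#' @param grid a [volume_grid].
#' @param path output path.
#' @param encoding `"raw"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  d <- dim(grid$values)
  s <- grid$spacing_cm
  hdr <- c("NRRD0004",
           "# epidose volume",
           "type: float",
           "dimension: 3",
           "space: left-posterior-superior",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                   s[1], s[2], s[3]),
           "kinds: domain domain domain",
           if (encoding == "raw") "endian: little",
           sprintf("encoding: %s", encoding),
           sprintf("space origin: (%.9g,%.9g,%.9g)",
                   grid$origin_cm[1], grid$origin_cm[2], grid$origin_cm[3]),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(grid$values), con, size = 4, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(grid$values), digits = 9),
                     collapse = " "), con)
  }
  invisible(path)
}

parse_nrrd_vectors <- function(x) {
  m <- regmatches(x, gregexpr("\\(([^)]*)\\)", x))[[1]]
  lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

#' Read a volume grid from NRRD
#'
#' Supports 3D `float`/`double` volumes with `raw` (little-endian) or
#' `ascii` encoding. Spacing must be present (`space directions` or
#' `spacings`); a missing spacing raises a metadata error.
#'
#' @param path NRRD file path.
#' @param kind grid kind passed to [volume_grid()].
#' @return a [volume_grid].
#' @export
read_volume <- function(path, kind = "generic") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("format error: not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[trimws(kv[2])]] <- kv[3]
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("format error: need a 3D volume")
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    spacing <- vapply(seq_along(dirs), function(i) dirs[[i]][i], numeric(1))
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  } else {
    stop("metadata error: missing voxel spacing")
  }
  origin <- if (!is.null(fields[["space origin"]]))
    parse_nrrd_vectors(fields[["space origin"]])[[1]]
  else c(0, 0, 0)
  n <- prod(sizes)
  enc <- trimws(fields$encoding)
  vals <- switch(enc,
    raw = {
      sz <- if (trimws(fields$type) %in% c("double", "float64")) 8L else 4L
      readBin(con, numeric(), n = n, size = sz, endian = "little")
    },
    ascii = ,
    text = as.numeric(scan(con, what = numeric(), n = n, quiet = TRUE)),
    stop("format error: unsupported encoding ", enc))
  if (length(vals) != n) stop("format error: truncated data block")
  volume_grid(array(vals, sizes), spacing, origin, kind = kind)
}

#' Write a fluence map as CSV (with pitch/origin header comments)
#' @param fluence a [fluence_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fluence_csv <- function(fluence, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spacing_cm %.9g", fluence$spacing_cm),
               sprintf("# origin_cm %.9g %.9g", fluence$origin_cm[1],
                       fluence$origin_cm[2])), con)
  write.table(fluence$values, con, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a fluence map written by [write_fluence_csv()]
#' @param path CSV path.
#' @return a [fluence_map].
#' @export
read_fluence_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  spacing <- as.numeric(sub("# spacing_cm ", "", hdr[1]))
  origin <- as.numeric(strsplit(sub("# origin_cm ", "", hdr[2]), " ")[[1]])
  vals <- as.matrix(read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(vals) <- NULL
  fluence_map(vals, spacing, origin)
}
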