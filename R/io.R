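#' Read a volume from disk
#'
#' Reads NRRD or NIfTI-1 into a [volume_grid()]. The header's spacing,
#' origin and axis directions are carried over; values stay in native units
#' (HU for CT, Gy for dose).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"nrrd"`, `"nifti"`; `"auto"` dispatches
#'   on the file extension (`.nrrd` / `.nii`, `.nii.gz`).
#' @return a `volume_grid`.
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read volume: no such file '%s'", path))
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
              else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
              else stop(sprintf("cannot infer volume format from '%s'", path))
  }
  switch(format, nrrd = read_nrrd(path), nifti = read_nifti_volume(path))
}

#' Write a volume to disk
#'
#' @param vol a `volume_grid` (or `roi_mask`).
#' @param path destination; extension selects the format when `format`
#'   is `"auto"`.
#' @param format `"auto"`, `"nrrd"` or `"nifti"`.
#' @param encoding NRRD data encoding: `"raw"` (little-endian binary) or
#'   `"ascii"` (plain text, written at full double precision so that a
#'   write/read round trip is bit exact).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "nrrd", "nifti"),
                         encoding = c("raw", "ascii")) {
  format <- match.arg(format)
  encoding <- match.arg(encoding)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti" else "nrrd"
  }
  switch(format,
         nrrd = write_nrrd(vol, path, encoding = encoding),
         nifti = write_nifti_volume(vol, path))
  invisible(path)
}

## ---- NRRD ------------------------------------------------------------------
## Minimal NRRD0004 support: attached header, 3-D scalar data, encodings
## "raw" (little-endian) and "ascii"/"text". This covers what 3D Slicer
## exports for CT / dose / label volumes.

parse_nrrd_triplets <- function(x) {
  m <- gregexpr("\\(([^)]*)\\)", x)[[1]]
  if (m[1] == -1) return(NULL)
  pieces <- regmatches(x, gregexpr("\\(([^)]*)\\)", x))[[1]]
  lapply(pieces, function(p)
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1]]))
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) == 0L || !grepl("^NRRD000", magic))
    stop(sprintf("'%s' is not an NRRD file (bad magic)", path))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop(sprintf("truncated NRRD header in '%s'", path))
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line))
    pos <- regexpr(":=?", line)
    if (pos == -1) next
    key <- tolower(trimws(substr(line, 1, pos - 1)))
    val <- trimws(substr(line, pos + attr(pos, "match.length"), nchar(line)))
    fields[[key]] <- val
  }
  if (is.null(fields$sizes) || is.null(fields$type))
    stop(sprintf("NRRD '%s' lacks required geometry metadata (sizes/type)", path))
  sizes <- as.integer(strsplit(fields$sizes, "[ \t]+")[[1]])
  if (length(sizes) != 3L)
    stop(sprintf("NRRD '%s': only 3-D scalar volumes are supported", path))
  n <- prod(sizes)
  enc <- tolower(if (is.null(fields$encoding)) "raw" else fields$encoding)
  type <- tolower(fields$type)
  if (enc %in% c("ascii", "txt", "text")) {
    txt <- readLines(con, warn = FALSE)
    vals <- as.numeric(scan(text = paste(txt, collapse = " "),
                            what = numeric(), quiet = TRUE))
  } else if (enc == "raw") {
    endian <- if (!is.null(fields$endian) && tolower(fields$endian) == "big")
      "big" else "little"
    vals <- switch(type,
      "double" = readBin(con, "double", n = n, size = 8, endian = endian),
      "float"  = readBin(con, "double", n = n, size = 4, endian = endian),
      "int" = , "signed int" = , "int32" =
        as.numeric(readBin(con, "integer", n = n, size = 4, endian = endian)),
      "short" = , "signed short" = , "int16" =
        as.numeric(readBin(con, "integer", n = n, size = 2, endian = endian)),
      "uchar" = , "unsigned char" = , "uint8" =
        as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
      stop(sprintf("NRRD '%s': unsupported type '%s'", path, type)))
  } else stop(sprintf("NRRD '%s': unsupported encoding '%s'", path, enc))
  if (length(vals) != n)
    stop(sprintf("truncated NRRD data in '%s': expected %d values, got %d",
                 path, n, length(vals)))
  # geometry: prefer space directions, fall back to spacings
  spacing <- c(1, 1, 1); direction <- diag(3); origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_triplets(fields[["space directions"]])
    if (length(dirs) == 3L) {
      M <- do.call(cbind, dirs)
      spacing <- sqrt(colSums(M^2))
      direction <- sweep(M, 2, spacing, "/")
    }
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "[ \t]+")[[1]])[1:3]
  }
  if (!is.null(fields[["space origin"]])) {
    o <- parse_nrrd_triplets(fields[["space origin"]])
    if (length(o) >= 1L) origin <- o[[1]]
  }
  volume_grid(array(vals, dim = sizes), spacing = spacing, origin = origin,
              direction = direction)
}

write_nrrd <- function(vol, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(vol, "volume_grid"))
  d <- dim(vol$values)
  M <- vol$direction %*% diag(vol$spacing)
  fmt3 <- function(v) sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
  hdr <- c("NRRD0004",
           "# generated by dosimix",
           "type: double",
           "dimension: 3",
           "space: left-posterior-superior",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("space directions: %s %s %s",
                   fmt3(M[, 1]), fmt3(M[, 2]), fmt3(M[, 3])),
           "kinds: domain domain domain",
           "endian: little",
           sprintf("encoding: %s", encoding),
           sprintf("space origin: %s", fmt3(vol$origin)),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (encoding == "raw") {
    writeBin(as.double(as.vector(vol$values)), con, size = 8, endian = "little")
  } else {
    writeLines(sprintf("%.17g", as.vector(vol$values)), con)
  }
  invisible(path)
}

## ---- NIfTI -----------------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI '%s': %s", path,
                                 conditionMessage(e))))
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop(sprintf("NIfTI '%s' is not 3-D", path))
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  direction <- sweep(xf[1:3, 1:3], 2, spacing, "/")
  origin <- xf[1:3, 4]
  volume_grid(vals, spacing = spacing, origin = origin, direction = direction)
}

write_nifti_volume <- function(vol, path) {
  xf <- diag(4)
  xf[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  xf[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- outcomes CSV ----------------------------------------------------------

#' Read an outcomes table
#'
#' CSV columns: `case_id`, `failure` (0/1), `time_months`, `competing_death`
#' (0/1).
#'
#' @param path CSV path.
#' @return data.frame with one row per case.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "failure", "time_months", "competing_death")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("outcomes CSV '%s' lacks columns: %s", path,
                 paste(miss, collapse = ", ")))
  df$failure <- as.integer(df$failure)
  df$competing_death <- as.integer(df$competing_death)
  if (any(df$failure == 1 & df$competing_death == 1))
    stop("a case cannot both fail and die of the competing cause")
  df
}

#' Write an outcomes table
#' @param cases list of `study_case` objects with outcomes.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(cases, path) {
  df <- do.call(rbind, lapply(cases, function(cs) {
    oc <- cs$outcome
    data.frame(case_id = cs$case_id,
               failure = as.integer(oc$failure),
               time_months = oc$time_months,
               competing_death = as.integer(oc$competing_death))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
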