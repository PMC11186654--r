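#' Write a scalar field as an NRRD volume
#'
#' Attached-header NRRD with double-precision little-endian raw data and
#' gzip encoding; spacing and origin are recorded in millimeters in the
#' `space directions` / `space origin` fields (the interchange convention
#' of treatment-planning viewers).  Values round-trip bit-exactly
#' through [readNRRD()].
#'
#' @param field a [ScalarField-class].
#' @param path output path (conventionally `.nrrd`).
#' @param content free-text content description stored in the header.
#' @return `path`, invisibly.
#' @examples
#' g <- VoxelGrid(dim = c(4, 4, 4), spacing = 5e-4)
#' f <- ScalarField(g, array(runif(64), c(4, 4, 4)), "dose")
#' p <- tempfile(fileext = ".nrrd")
#' writeNRRD(f, p)
#' identical(fieldValues(readNRRD(p)), fieldValues(f))
#' @export
writeNRRD <- function(field, path, content = field@kind) {
  stopifnot(is(field, "ScalarField"))
  v <- field@values
  if (any(!is.finite(v))) stopf("cannot export non-finite field values")
  g <- field@grid
  sp <- g@spacing * 1e3
  or <- g@origin * 1e3
  header <- c(
    "NRRD0004",
    sprintf("# %s volume written by iustherm", content),
    "type: double",
    "dimension: 3",
    "space dimension: 3",
    sprintf("sizes: %d %d %d", g@dim[1], g@dim[2], g@dim[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            sp[1], sp[2], sp[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)", or[1], or[2], or[3]),
    "space units: \"mm\" \"mm\" \"mm\"",
    "endian: little",
    "encoding: gzip",
    ""
  )
  ## gzip the payload through a gzcon-wrapped connection (true gzip stream)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  gz <- gzcon(file(tmp, "wb"))
  writeBin(as.double(v), gz, size = 8, endian = "little")
  close(gz)
  con <- file(path, "wb")
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(readBin(tmp, "raw", file.size(tmp)), con)
  close(con)
  invisible(path)
}

#' Read an NRRD volume into a scalar field
#'
#' Supports the subset written by [writeNRRD()]: attached header, 3D
#' double/float data, gzip or raw encoding, little endian, axis-aligned
#' `space directions`.
#'
#' @param path NRRD file path.
#' @param kind field kind to tag the result with (default `"generic"`).
#' @return a [ScalarField-class].
#' @export
readNRRD <- function(path, kind = "generic") {
  if (!file.exists(path)) stopf("NRRD file not found: %s", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 16 || !identical(rawToChar(raw[1:4]), "NRRD"))
    stopf("not an NRRD file: %s", path)
  nl <- as.raw(10)
  split <- which(raw[-length(raw)] == nl & raw[-1] == nl)
  if (!length(split)) stopf("malformed NRRD (no header terminator): %s", path)
  split <- split[1]
  header <- strsplit(rawToChar(raw[seq_len(split - 1)]), "\n", fixed = TRUE)[[1]]
  payload <- raw[(split + 2):length(raw)]

  fieldOf <- function(key) {
    ln <- grep(sprintf("^%s: ", key), header, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(sprintf("^%s: ", key), "", ln[1])
  }
  sizes <- as.integer(strsplit(fieldOf("sizes") %||%
                                 stopf("NRRD missing sizes: %s", path), " ")[[1]])
  if (length(sizes) != 3L) stopf("only 3D NRRD volumes are supported")
  type <- fieldOf("type") %||% "double"
  enc <- fieldOf("encoding") %||% "raw"
  endian <- fieldOf("endian") %||% "little"
  numbers <- function(s) as.numeric(regmatches(s,
    gregexpr("-?[0-9.eE+]+", s))[[1]])
  dirs <- fieldOf("space directions")
  spacing <- if (is.null(dirs)) rep(1, 3) else {
    m <- matrix(numbers(dirs), nrow = 3, byrow = TRUE)
    if (any(abs(m[cbind(c(1, 2, 3), c(2, 3, 1))]) > 0) ||
        any(abs(m[cbind(c(1, 2, 3), c(3, 1, 2))]) > 0))
      stopf("only axis-aligned space directions are supported")
    diag(m)
  }
  origin <- if (is.null(fieldOf("space origin"))) rep(0, 3)
            else numbers(fieldOf("space origin"))

  sz <- switch(type, double = 8L, float = 4L,
               stopf("unsupported NRRD type '%s'", type))
  n <- prod(sizes)
  values <- switch(enc,
    gzip = {
      gz <- gzcon(rawConnection(payload, "rb"))
      on.exit(close(gz), add = TRUE)
      tryCatch(readBin(gz, "numeric", n = n, size = sz, endian = endian),
               error = function(e) stopf("corrupt gzip payload in %s", path))
    },
    raw = {
      if (length(payload) < n * sz) stopf("truncated NRRD payload in %s", path)
      readBin(payload, "numeric", n = n, size = sz, endian = endian)
    },
    stopf("unsupported NRRD encoding '%s'", enc))
  if (length(values) < n) stopf("truncated NRRD payload in %s", path)
  grid <- VoxelGrid(dim = sizes, spacing = spacing / 1e3, origin = origin / 1e3)
  ScalarField(grid, array(values, dim = sizes), kind = kind)
}
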