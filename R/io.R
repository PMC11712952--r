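# File round-tripping: MetaImage (MHD header + raw payload) voxel grids,
# CSV histograms/tables, and a strict YAML run configuration.

#' Write a voxel map as a MetaImage (MHD + raw) pair
#'
#' Text key = value header with full-precision origin/spacing metadata and
#' a raw binary payload (`MET_DOUBLE`), so the round trip is lossless.
#'
#' @param map 3D array.
#' @param grid Its [voxel_grid()].
#' @param path Header path (`.mhd`); the payload goes next to it (`.raw`).
#' @param msb Write the payload big-endian.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(map, grid, path, msb = FALSE) {
  stopifnot(length(dim(map)) == 3, identical(dim(map), as.integer(grid$dims)))
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  if (raw_name == basename(path)) raw_name <- paste0(basename(path), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    sprintf("DimSize = %d %d %d", dim(map)[1], dim(map)[2], dim(map)[3]),
    sprintf(
      "ElementSpacing = %.17g %.17g %.17g",
      grid$spacing[1], grid$spacing[2], grid$spacing[3]
    ),
    sprintf(
      "Offset = %.17g %.17g %.17g",
      grid$origin[1], grid$origin[2], grid$origin[3]
    ),
    sprintf("BinaryDataByteOrderMSB = %s", if (msb) "True" else "False"),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(map), con,
    size = 8,
    endian = if (msb) "big" else "little"
  )
  invisible(path)
}

parse_mhd_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  h <- setNames(as.list(vals), keys)
  need <- c("DimSize", "ElementSpacing", "Offset", "ElementType",
            "ElementDataFile")
  for (k in need) {
    if (is.null(h[[k]]) || !nzchar(h[[k]])) {
      abort(sprintf("malformed MHD header: missing field '%s'", k))
    }
  }
  h
}

#' Read a MetaImage voxel map
#'
#' @param path Header path (`.mhd`).
#' @return List with `map` (3D array) and `grid` ([voxel_grid()]).
#' @export
read_mhd <- function(path) {
  h <- parse_mhd_header(path)
  dims <- as.integer(strsplit(h$DimSize, "\\s+")[[1]])
  if (length(dims) != 3 || any(is.na(dims))) {
    abort("malformed MHD header: field 'DimSize' is not three integers")
  }
  spacing <- as.numeric(strsplit(h$ElementSpacing, "\\s+")[[1]])
  origin <- as.numeric(strsplit(h$Offset, "\\s+")[[1]])
  if (!identical(h$ElementType, "MET_DOUBLE")) {
    abort(sprintf(
      "malformed MHD header: unsupported ElementType '%s'", h$ElementType
    ))
  }
  msb <- identical(h$BinaryDataByteOrderMSB, "True")
  raw_path <- file.path(dirname(path), h$ElementDataFile)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric",
    n = prod(dims), size = 8,
    endian = if (msb) "big" else "little"
  )
  if (length(v) != prod(dims)) abort("raw payload shorter than DimSize")
  list(map = array(v, dims), grid = voxel_grid(origin, spacing, dims))
}

#' Write and read histogram / table CSVs
#'
#' Thin wrappers with a stable column order for spectra, feature tables
#' and volume-histogram curves.
#'
#' @param x Data frame.
#' @param path CSV path.
#' @return `path` / tibble.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  as_tibble(read.csv(path))
}

run_config_defaults <- function() {
  list(
    energy = 150, scenario = "uncollimated", offset = 0,
    histories = 1e5, seed = 1L,
    grid_spacing = 0.1,
    prescription = 25, target = "cube", lambda = 0.05,
    nuclear_model = TRUE, straggling = TRUE, scattering = TRUE
  )
}

#' Read a run configuration (strict YAML)
#'
#' Unknown keys are rejected; all omitted keys take the documented
#' defaults; every seed is explicit in the returned object.
#'
#' @param path YAML file.
#' @return Named list of stage parameters with a provenance stamp
#'   (`config_hash`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown config keys: %s", paste(unknown, collapse = ", ")
    ))
  }
  out <- modifyList(defaults, cfg)
  out$config_hash <- sprintf(
    "%08x",
    sum(utf8ToInt(paste(names(out), unlist(lapply(out, format)),
      collapse = ";"
    )) * seq_along(utf8ToInt(paste(names(out),
      unlist(lapply(out, format)),
      collapse = ";"
    )))) %% .Machine$integer.max
  )
  out
}
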