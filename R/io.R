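# MetaImage (.mhd/.raw) volume I/O with JSON sidecars, projection-set I/O,
# and run configuration handling. MetaImage was chosen for its losslessness
# and trivially parseable text header; no installed R package reads it, so
# the reader/writer is implemented here.

#' Write a volume as MetaImage with a JSON sidecar
#'
#' @param data Numeric 3-D array.
#' @param path Path ending in `.mhd`; the raw data file and a `.json`
#'   sidecar are written next to it.
#' @param spacing Voxel spacing, mm (length 3).
#' @param sidecar Named list of metadata (units, provenance, seeds...).
#' @param element_type `"MET_DOUBLE"` or `"MET_FLOAT"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1), sidecar = list(),
                         element_type = c("MET_DOUBLE", "MET_FLOAT")) {
  element_type <- match.arg(element_type)
  stopifnot(length(dim(data)) == 3, grepl("\\.mhd$", path))
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(dim(data), collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing, digits = 17), collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", raw_name))
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.double(as.vector(data)), con,
           size = if (element_type == "MET_DOUBLE") 8 else 4,
           endian = "little")
  jsonlite::write_json(c(sidecar, list(dim = dim(data), spacing = spacing)),
                       sub("\\.mhd$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a MetaImage volume (with its JSON sidecar if present)
#'
#' @param path Path to the `.mhd` header.
#' @return List with `data` (array), `spacing`, `sidecar`.
#' @export
read_volume <- function(path) {
  lines <- readLines(path)
  field <- function(key) {
    ln <- grep(paste0("^", key, " *="), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  et <- field("ElementType")
  if (!et %in% c("MET_DOUBLE", "MET_FLOAT")) {
    stop("unsupported MetaImage element type: ", et %||% "<missing>")
  }
  dims <- as.integer(strsplit(field("DimSize"), " +")[[1]])
  spacing <- as.numeric(strsplit(field("ElementSpacing"), " +")[[1]])
  raw_path <- file.path(dirname(path), field("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(dims),
                  size = if (et == "MET_DOUBLE") 8 else 4, endian = "little")
  side_path <- sub("\\.mhd$", ".json", path)
  sidecar <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  }
  list(data = array(vals, dim = dims), spacing = spacing, sidecar = sidecar)
}

#' Write a projection set (one MetaImage stack per window + sidecar)
#'
#' @param proj A `projection_set`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return `dir`, invisibly.
#' @export
write_projections <- function(proj, dir, prefix = "proj") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- proj$geometry
  for (w in names(proj$counts)) {
    write_volume(proj$counts[[w]],
                 file.path(dir, paste0(prefix, "_", w, ".mhd")),
                 spacing = c(g$pitch_mm, g$pitch_mm, 1))
  }
  meta <- list(kind = "projection_set",
               windows = lapply(g$windows, unclass),
               n_angles = g$n_angles, arc_deg = g$arc_deg,
               radius_cm = g$radius_cm, nu = g$nu, nv = g$nv,
               pitch_mm = g$pitch_mm,
               time_per_angle_s = g$time_per_angle_s,
               sensitivity = g$sensitivity,
               seed = proj$seed, n_histories = proj$n_histories,
               poisson = proj$poisson, prefix = prefix)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_set.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a projection set written by [write_projections()]
#'
#' @param dir Directory.
#' @param prefix File name prefix.
#' @return A `projection_set`.
#' @export
read_projections <- function(dir, prefix = "proj") {
  meta_path <- file.path(dir, paste0(prefix, "_set.json"))
  if (!file.exists(meta_path)) stop("no projection-set sidecar at ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  wins <- lapply(meta$windows, function(w)
    energy_window(w$label, w$center, w$width_fraction))
  geom <- acquisition_geometry(
    n_angles = meta$n_angles, arc_deg = meta$arc_deg,
    radius_cm = meta$radius_cm, nu = meta$nu, nv = meta$nv,
    pitch_mm = meta$pitch_mm, windows = wins,
    time_per_angle_s = meta$time_per_angle_s,
    sensitivity = meta$sensitivity)
  counts <- list()
  for (w in names(wins)) {
    p <- file.path(dir, paste0(prefix, "_", w, ".mhd"))
    if (!file.exists(p)) stop("missing window stack: ", p)
    v <- read_volume(p)
    if (!identical(dim(v$data), c(geom$nu, geom$nv, geom$n_angles))) {
      stop("stack shape mismatch for window ", w)
    }
    counts[[w]] <- v$data
  }
  new_projection_set(counts, geom,
                     seed = meta$seed %||% NA_integer_,
                     n_histories = meta$n_histories %||% NA_real_,
                     poisson = isTRUE(meta$poisson))
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file.
#' @return `read_run_config`: named list; `write_run_config`: `path`
#'   invisibly.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config Named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Stable hash of a configuration (FNV-1a over its canonical JSON)
#'
#' @param config Named list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  mult <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit modular multiply in exact double arithmetic
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * mult) %% 4294967296 * 65536 + lo * mult) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
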