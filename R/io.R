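# ---- NIfTI, CSV and JSON interfaces ------------------------------------

#' Read a NIfTI volume as array plus grid info
#'
#' @param path `.nii` / `.nii.gz` file.
#' @return list: `data` (3D array), `spacing` (dx, dy, dz in mm).
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  list(data = as.array(img), spacing = as.numeric(sp[1:3]))
}

#' Read a Dixon fat/water pair into a stack
#'
#' @param fat_path,water_path NIfTI files on the same grid.
#' @param axis_offset_mm,distal_first stack placement, see [dixon_stack()].
#' @return A [dixon_stack()].
#' @export
read_dixon_pair <- function(fat_path, water_path, axis_offset_mm = 0,
                            distal_first = TRUE) {
  f <- read_nifti_volume(fat_path)
  w <- read_nifti_volume(water_path)
  dixon_stack(f$data, w$data, spacing = f$spacing,
              axis_offset_mm = axis_offset_mm, distal_first = distal_first)
}

#' Write a volume to NIfTI
#'
#' @param x an [ff_volume()], [dixon_stack()] field, or plain 3D array.
#' @param path output `.nii.gz` path.
#' @param spacing voxel spacing when `x` is a plain array.
#' @export
write_nifti_volume <- function(x, path, spacing = c(1.36, 1.36, 5)) {
  if (inherits(x, "ff_volume")) {
    spacing <- x$spacing
    x <- x$ff
  }
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a muscle label map and its table
#'
#' @param labels_path NIfTI integer label volume.
#' @param table_path CSV with columns `label`, `muscle`, `side`, `region`,
#'   `compartment`.
#' @param exclusions_path optional CSV with columns `muscle`, `side`,
#'   `timepoint`.
#' @return A [muscle_label_map()].
#' @export
read_label_map <- function(labels_path, table_path, exclusions_path = NULL) {
  lab <- read_nifti_volume(labels_path)
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  exc <- if (!is.null(exclusions_path)) {
    utils::read.csv(exclusions_path, stringsAsFactors = FALSE)
  }
  storage.mode(lab$data) <- "integer"
  muscle_label_map(lab$data, tab, exc)
}

#' Drop excluded muscles from a profile list
#'
#' Removes profiles whose (muscle, side, timepoint) appears on the
#' exclusion list (e.g. fat-water-swapped muscles, excluded manually).
#'
#' @param profiles list of [muscle_profile()].
#' @param exclusions data.frame with `muscle`, `side`, `timepoint`.
#' @return filtered list.
#' @export
apply_exclusions <- function(profiles, exclusions) {
  if (is.null(exclusions) || !nrow(exclusions)) return(profiles)
  keys <- with(exclusions, paste(muscle, side, timepoint, sep = "|"))
  keep <- vapply(profiles, function(p) {
    !(paste(p$muscle, p$side, p$timepoint, sep = "|") %in% keys)
  }, TRUE)
  profiles[keep]
}

#' Rebuild profile objects from a per-slice table
#'
#' Inverse of [profile_table()]: groups rows by muscle, side and timepoint.
#'
#' @param df data.frame with columns `muscle`, `side`, `timepoint`,
#'   `slice_index`, `ff`, `n_voxels`.
#' @return list of [muscle_profile()].
#' @export
profiles_from_table <- function(df) {
  key <- interaction(df$muscle, df$side, df$timepoint, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$slice_index), ]
    muscle_profile(g$muscle[1], g$side[1], g$timepoint[1],
                   g$slice_index, g$ff, g$n_voxels)
  })
}

#' Write a data.frame as deterministic CSV
#'
#' Fixed column order (as given), '.' decimal separator, no row names.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a schema-versioned JSON report
#'
#' @param x list to serialize.
#' @param path output path.
#' @param schema report schema tag.
#' @export
write_json_report <- function(x, path, schema = "fatfront/1") {
  jsonlite::write_json(c(list(schema = schema), x), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a run configuration (YAML or JSON)
#'
#' @param path configuration file; `.yaml`/`.yml` parsed with yaml,
#'   anything else as JSON.
#' @return named list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
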