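#' Write quantitative maps as NIfTI volumes
#'
#' One float32 NIfTI file per map (`t1.nii.gz`, `t2.nii.gz`, `pd.nii.gz`,
#' `vista.nii.gz`, and `mwf.nii.gz` / `b1.nii.gz` when present), with the
#' voxel size carried in the header, plus a JSON manifest.
#'
#' @param qmaps a [fit_maps()] result (optionally with `$mwf_map` added).
#' @param dir output directory (created if needed).
#' @param voxel_size isotropic voxel edge in mm.
#' @param manifest optional named list merged into the JSON manifest.
#' @return the directory, invisibly.
#' @export
write_quant_maps <- function(qmaps, dir, voxel_size = 1, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- list(t1 = qmaps$t1_map, t2 = qmaps$t2_map, pd = qmaps$pd_map,
               vista = qmaps$vista_image)
  if (!is.null(qmaps$mwf_map)) vols$mwf <- qmaps$mwf_map
  if (!is.null(qmaps$b1_map_used)) vols$b1 <- qmaps$b1_map_used
  for (nm in names(vols)) {
    img <- RNifti::asNifti(vols[[nm]],
                           pixdim = rep(voxel_size, 3), datatype = "float")
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  mf <- utils::modifyList(list(package = "vistamrf",
                               version = as.character(utils::packageVersion("vistamrf")),
                               maps = names(vols),
                               voxel_size_mm = voxel_size,
                               units = list(t1 = "ms", t2 = "ms",
                                            pd = "a.u.", mwf = "fraction"),
                               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                          manifest)
  jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_quant_maps
#' @param path directory written by `write_quant_maps`.
#' @export
read_quant_maps <- function(path) {
  rd <- function(nm) {
    f <- file.path(path, paste0(nm, ".nii.gz"))
    if (file.exists(f)) {
      x <- RNifti::readNifti(f)
      array(as.numeric(x), dim(x))
    } else NULL
  }
  structure(list(t1_map = rd("t1"), t2_map = rd("t2"), pd_map = rd("pd"),
                 vista_image = rd("vista"), mwf_map = rd("mwf"),
                 b1_map_used = rd("b1")),
            class = "quant_maps")
}

#' Run manifest written next to pipeline outputs
#'
#' Records the package version, seeds, and a hash of every configuration
#' object so a run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param seeds named list/vector of seeds.
#' @param configs named list of configuration objects (hashed).
#' @param extra named list merged verbatim.
#' @export
write_run_manifest <- function(path, seeds = list(), configs = list(),
                               extra = list()) {
  hashes <- lapply(configs, function(x) {
    s <- paste(deparse(x), collapse = "")
    h <- 0
    for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
    sprintf("%d", h)
  })
  jsonlite::write_json(utils::modifyList(list(
    package = "vistamrf",
    version = as.character(utils::packageVersion("vistamrf")),
    seeds = seeds, config_hashes = hashes,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
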