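# Writers for curves, fields and summaries.  Units are fixed project-wide
# (mm, N, MPa, dimensionless strain) and stated in every file header.

#' Check that an output directory is writable
#'
#' Intended to be called before a long run starts, so an unwritable target
#' fails early rather than after minutes of computation.
#'
#' @param out_dir Directory path (created if missing).
#' @return `out_dir`, invisibly.
#' @export
check_output_dir <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write-probe")
  ok <- tryCatch({
    writeLines("x", probe)
    unlink(probe)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("output directory is not writable: ", out_dir, call. = FALSE)
  invisible(out_dir)
}

#' Write all artifacts of one completed run
#'
#' Writes `curve.csv` (load-displacement history), `field.vtu` (unstructured
#' grid with per-element damage and failed flag, openable in standard VTK
#' viewers), `summary.json` (fracture summary + termination + resolved
#' configuration echo + geometry hash + package version) and `run.log`
#' (per-increment lines).  Outputs are deterministic: identical config and
#' seed reproduce byte-identical `curve.csv` and `summary.json`.
#'
#' @param result A [run_compression()] result.
#' @param summary A [summarize_fracture()] summary.
#' @param mesh The mesh used.
#' @param out_dir Output directory (created if needed, checked writable).
#' @param config Optional resolved [load_config()] echoed into the summary.
#' @param geometry_hash Optional [specimen_hash()] string.
#' @param write_vtu Write the `field.vtu` cell-data file.
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, summary, mesh, out_dir,
                          config = NULL, geometry_hash = NULL,
                          write_vtu = TRUE) {
  check_output_dir(out_dir)
  files <- c()

  curve_path <- file.path(out_dir, "curve.csv")
  con <- file(curve_path, "w")
  writeLines(c("# cdmbone load-displacement record",
               "# units: displacement mm, reaction N"), con)
  utils::write.csv(result$records, con, row.names = FALSE)
  close(con)
  files["curve"] <- curve_path

  summary_path <- file.path(out_dir, "summary.json")
  payload <- list(
    units = list(displacement = "mm", force = "N", modulus = "MPa",
                 strain = "dimensionless"),
    summary = unclass(summary),
    termination = result$termination,
    criterion = result$criterion,
    n_elements = result$n_elements,
    stagger_warnings = result$stagger_warnings,
    boundary_note = paste("rigid platen contact approximated by nodal",
                          "constraints (bottom frictionless, top",
                          result$bcs$top, ")"),
    package_version = as.character(utils::packageVersion("cdmbone")),
    geometry_hash = geometry_hash,
    config = if (!is.null(config)) unclass(config) else NULL,
    config_hash = if (!is.null(config)) attr(config, "hash") else NULL)
  jsonlite::write_json(payload, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files["summary"] <- summary_path

  if (write_vtu) {
    vtu_path <- file.path(out_dir, "field.vtu")
    write_vtu_field(mesh, list(D = result$D,
                               failed = as.integer(result$failed)),
                    vtu_path)
    files["field"] <- vtu_path
  }

  log_path <- file.path(out_dir, "run.log")
  r <- result$records
  writeLines(c(
    sprintf("# cdmbone run log (%s criterion, %d elements)",
            result$criterion, result$n_elements),
    "# units: displacement mm, reaction N",
    sprintf("inc %3d  u=%.5f  R=%.4f  damaged=%d  failed=%d  maxD=%.4f  iters=%d%s",
            seq_len(nrow(r)) - 1, r$displacement, r$reaction, r$n_damaged,
            r$n_failed, r$max_D, r$stagger_iterations,
            ifelse(r$converged, "", "  NOT-CONVERGED")),
    sprintf("terminated: %s", result$termination)), log_path)
  files["log"] <- log_path

  invisible(files)
}

#' Write an unstructured-grid VTU file with per-element scalar fields
#'
#' ASCII XML `UnstructuredGrid` (VTK hexahedron cells, type 12), one value
#' per cell for each field.
#'
#' @param mesh A [voxels_to_mesh()] mesh.
#' @param cell_data Named list of numeric vectors, one value per element.
#' @param path Output `.vtu` path.
#' @return `path`, invisibly.
#' @export
write_vtu_field <- function(mesh, cell_data, path) {
  np <- nrow(mesh$nodes)
  nc <- nrow(mesh$elements)
  stopifnot(all(vapply(cell_data, length, 0L) == nc))
  fmt <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                           collapse = " ")
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <!-- cdmbone damage field; coordinates in mm -->',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste0("          ", apply(mesh$nodes, 1, fmt)),
    '        </DataArray>',
    '      </Points>',
    '      <Cells>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste0("          ", apply(mesh$elements - 1L, 1, fmt)),
    '        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste0("          ", fmt(8L * seq_len(nc))),
    '        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">',
    paste0("          ", fmt(rep(12L, nc))),
    '        </DataArray>',
    '      </Cells>',
    sprintf('      <CellData Scalars="%s">', names(cell_data)[1]),
    unlist(lapply(names(cell_data), function(nm) c(
      sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm),
      paste0("          ", fmt(as.numeric(cell_data[[nm]]))),
      '        </DataArray>'))),
    '      </CellData>',
    '    </Piece>',
    '  </UnstructuredGrid>',
    '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}
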