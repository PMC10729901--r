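## Plain-text interchange: ASCII PLY for meshes and per-vertex scalars,
## wide CSV (patients x vertices) for maps, CSV for the clinical table,
## YAML for generator configurations.

#' Write a template mesh (with optional per-vertex scalar) as ASCII PLY
#'
#' Per-vertex properties: x, y, z, nx, ny, nz, region (uchar code into the
#' 12-region level set), area (float), plus one optional named scalar.
#'
#' @param mesh a \linkS4class{TemplateMesh}.
#' @param path output file.
#' @param scalar optional per-vertex numeric vector.
#' @param scalarName property name for \code{scalar}.
#' @export
writeTemplatePLY <- function(mesh, path, scalar = NULL,
                             scalarName = "thickness") {
  nv <- nrow(mesh@vertices)
  hdr <- c("ply", "format ascii 1.0",
           paste("comment region codes:",
                 paste(seq_along(levels(mesh@region)) - 1L,
                       levels(mesh@region), sep = "=", collapse = " ")),
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           "property uchar region", "property float area",
           if (!is.null(scalar)) paste("property float", scalarName),
           paste("element face", nrow(mesh@faces)),
           "property list uchar int vertex_indices", "end_header")
  vtab <- cbind(mesh@vertices, mesh@normals,
                as.integer(mesh@region) - 1L, mesh@vertexArea)
  if (!is.null(scalar)) vtab <- cbind(vtab, scalar)
  vlines <- do.call(paste, c(as.data.frame(vtab), list(sep = " ")))
  flines <- paste(3L, mesh@faces[, 1] - 1L, mesh@faces[, 2] - 1L,
                  mesh@faces[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY written by \code{\link{writeTemplatePLY}}
#'
#' @param path PLY file.
#' @return list with \code{vertices}, \code{faces} (1-based), \code{region}
#'   (integer codes), \code{area}, \code{normals} and any extra scalar.
#' @export
readPLY <- function(path) {
  lines <- readLines(path)
  endH <- which(lines == "end_header")
  hdr <- lines[seq_len(endH)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex",
                                                   hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face",
                                                 hdr, value = TRUE)))
  props <- sub("^property \\S+ ", "",
               grep("^property (float|uchar) ", hdr, value = TRUE))
  vtab <- utils::read.table(text = lines[endH + seq_len(nv)])
  colnames(vtab) <- props
  ftab <- utils::read.table(text = lines[endH + nv + seq_len(nf)])
  out <- list(vertices = unname(as.matrix(vtab[, c("x", "y", "z")])),
              normals = unname(as.matrix(vtab[, c("nx", "ny", "nz")])),
              region = as.integer(vtab$region),
              area = vtab$area,
              faces = unname(as.matrix(ftab[, 2:4]) + 1L))
  extra <- setdiff(props, c("x", "y", "z", "nx", "ny", "nz", "region", "area"))
  for (nm in extra) out[[nm]] <- vtab[[nm]]
  out
}

#' Write per-vertex maps as wide CSV
#'
#' Row = patient id, columns v0000...vNNNN, one file per cardiac phase.
#'
#' @param maps patients x vertices matrix with patient rownames.
#' @param path output CSV.
#' @export
writeVertexMapsCSV <- function(maps, path) {
  maps <- as.matrix(maps)
  dt <- data.table::data.table(
    id = if (is.null(rownames(maps))) sprintf("pat%04d", seq_len(nrow(maps)))
         else rownames(maps))
  vt <- data.table::as.data.table(maps)
  data.table::setnames(vt, sprintf("v%04d", seq_len(ncol(maps)) - 1L))
  data.table::fwrite(cbind(dt, vt), path)
  invisible(path)
}

#' Read wide-CSV per-vertex maps
#'
#' @param path CSV written by \code{\link{writeVertexMapsCSV}}.
#' @return patients x vertices matrix with patient-id rownames.
#' @export
readVertexMapsCSV <- function(path) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Export a cohort to a directory of plain-text files
#'
#' Writes template.ply, maps_ed.csv, maps_es.csv and clinical.csv.
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @param dir output directory (created if needed).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTemplatePLY(templateMesh(cohort), file.path(dir, "template.ply"))
  writeVertexMapsCSV(thicknessMaps(cohort, "ED"), file.path(dir, "maps_ed.csv"))
  writeVertexMapsCSV(thicknessMaps(cohort, "ES"), file.path(dir, "maps_es.csv"))
  clin <- clinicalTable(cohort)
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read a generator configuration as YAML
#'
#' Function-valued archetype fields are represented by name only; reading
#' restores the defaults for them.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param path YAML file.
#' @export
writeConfigYAML <- function(config, path) {
  ## named atomic vectors become YAML maps (as.list), recursively
  toTree <- function(x) {
    if (is.list(x)) lapply(x, toTree)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  cfg <- unclass(config)
  cfg$archetypes <- lapply(cfg$archetypes, function(a)
    a[setdiff(names(a), "field")])
  yaml::write_yaml(toTree(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname writeConfigYAML
#' @export
readConfigYAML <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- defaultArchetypes()
  names(defaults) <- vapply(defaults, `[[`, character(1), "name")
  raw$archetypes <- lapply(raw$archetypes, function(a) {
    a$field <- defaults[[a$name]]$field
    a
  })
  for (nm in c("genotypeProbs"))
    raw[[nm]] <- unlist(raw[[nm]])
  raw$effectSpec <- lapply(raw$effectSpec, unlist)
  raw$covariateModel <- lapply(raw$covariateModel, unlist)
  raw$pgsModel <- lapply(raw$pgsModel, unlist)
  raw$hazardModel[c("logHR")] <- list(unlist(raw$hazardModel$logHR))
  do.call(cohortConfig, raw[setdiff(names(raw), c())])
}
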