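#' Read a centerline model from file
#'
#' Three dialects are supported, all in millimetres with 0-based point
#' indices in the branching sections:
#' \describe{
#'   \item{csv}{header \code{x,y[,z],r}, one point per row; branching is
#'     encoded in trailing comment lines of the form
#'     \code{#polyline 0,1,2,...} listing point-index runs.}
#'   \item{json}{object with \code{dimension}, \code{points} (array of
#'     N-vectors), \code{radii}, optional \code{polylines} (arrays of
#'     0-based indices), \code{name}, \code{start_index}, \code{goal_index},
#'     \code{curvature_limit}.}
#'   \item{vtp}{VTK XML PolyData in the VMTK convention: polylines with the
#'     per-point radius stored in a PointData array named
#'     \code{MaximumInscribedSphereRadius}; 2D models carry z = 0 and a
#'     \code{Dimensionality} field-data array.}
#' }
#'
#' @param path file to read.
#' @param format one of \code{"vtp"}, \code{"csv"}, \code{"json"}; guessed
#'   from the file extension when missing.
#' @return a \code{\link{centerline_model}}; indices are assigned in file
#'   order.
#' @export
read_centerlines <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- format %||% guess_format(path)
  switch(format,
         csv = read_centerlines_csv(path),
         json = read_centerlines_json(path),
         vtp = read_centerlines_vtp(path),
         stopf("unknown format '%s' (use vtp, csv or json)", format))
}

#' Write a centerline model to file
#'
#' Inverse of \code{\link{read_centerlines}}; positions and radii
#' round-trip to within 1e-9 relative error in every dialect.
#'
#' @param model a \code{centerline_model}.
#' @param path output file.
#' @param format one of \code{"vtp"}, \code{"csv"}, \code{"json"}; guessed
#'   from the extension when missing.
#' @export
write_centerlines <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "centerline_model"))
  if (nrow(model$points) < 1L) stopf("model has no points")
  format <- format %||% guess_format(path)
  switch(format,
         csv = write_centerlines_csv(model, path),
         json = write_centerlines_json(model, path),
         vtp = write_centerlines_vtp(model, path),
         stopf("unknown format '%s' (use vtp, csv or json)", format))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("vtp", "csv", "json")) ext
  else stopf("cannot guess format from extension '%s'", ext)
}

# -- CSV ---------------------------------------------------------------------

read_centerlines_csv <- function(path) {
  lines <- readLines(path)
  pl_lines <- grep("^#polyline", lines, value = TRUE)
  data_lines <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(data_lines, collapse = "\n"))
  cols <- names(df)
  if (!"r" %in% cols) stopf("format error: expected a radius column named 'r'")
  coord_cols <- intersect(c("x", "y", "z"), cols)
  if (!all(c("x", "y") %in% coord_cols)) stopf("format error: expected coordinate columns x,y[,z]")
  pts <- as.matrix(df[, coord_cols, drop = FALSE])
  polylines <- if (length(pl_lines)) {
    lapply(pl_lines, function(s) {
      as.integer(strsplit(sub("^#polyline\\s+", "", s), ",")[[1L]]) + 1L
    })
  } else NULL
  centerline_model(pts, df$r, polylines = polylines)
}

write_centerlines_csv <- function(model, path) {
  df <- as.data.frame(model$points)
  names(df) <- c("x", "y", "z")[seq_len(model$N)]
  df$r <- model$radii
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  for (pl in model$polylines) {
    writeLines(paste0("#polyline ", paste(pl - 1L, collapse = ",")), con)
  }
}

# -- JSON --------------------------------------------------------------------

read_centerlines_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$radii)) stopf("format error: expected field 'radii'")
  pts <- as.matrix(obj$points)
  polylines <- if (!is.null(obj$polylines)) {
    pl <- obj$polylines
    if (is.matrix(pl)) pl <- lapply(seq_len(nrow(pl)), function(i) pl[i, ])
    lapply(pl, function(v) as.integer(v) + 1L)
  } else NULL
  centerline_model(pts, obj$radii, polylines = polylines, name = obj$name,
                   start_index = if (is.null(obj$start_index)) NULL else obj$start_index + 1L,
                   goal_index = if (is.null(obj$goal_index)) NULL else obj$goal_index + 1L,
                   curvature_limit = obj$curvature_limit)
}

write_centerlines_json <- function(model, path) {
  obj <- list(name = model$name, dimension = model$N,
              points = model$points, radii = model$radii,
              polylines = lapply(model$polylines, function(v) v - 1L))
  if (!is.null(model$start_index)) obj$start_index <- model$start_index - 1L
  if (!is.null(model$goal_index)) obj$goal_index <- model$goal_index - 1L
  if (!is.null(model$curvature_limit)) obj$curvature_limit <- model$curvature_limit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
}

# -- VTK PolyData (.vtp), ASCII, VMTK radius array ---------------------------

read_centerlines_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (is.na(piece)) stopf("format error: no <Piece> in PolyData file")
  num_arr <- function(node) scan(text = xml2::xml_text(node), quiet = TRUE)
  pts_node <- xml2::xml_find_first(piece, ".//Points/DataArray")
  coords <- matrix(num_arr(pts_node), ncol = 3L, byrow = TRUE)
  rad_node <- xml2::xml_find_first(
    piece, ".//PointData/DataArray[@Name='MaximumInscribedSphereRadius']")
  if (is.na(rad_node))
    stopf("format error: expected PointData array 'MaximumInscribedSphereRadius'")
  radii <- num_arr(rad_node)
  conn_node <- xml2::xml_find_first(piece, ".//Lines/DataArray[@Name='connectivity']")
  offs_node <- xml2::xml_find_first(piece, ".//Lines/DataArray[@Name='offsets']")
  polylines <- NULL
  if (!is.na(conn_node) && !is.na(offs_node)) {
    conn <- as.integer(num_arr(conn_node)) + 1L
    offs <- as.integer(num_arr(offs_node))
    starts <- c(1L, utils::head(offs, -1L) + 1L)
    polylines <- Map(function(s, e) conn[s:e], starts, offs)
  }
  dim_node <- xml2::xml_find_first(
    doc, ".//FieldData/DataArray[@Name='Dimensionality']")
  N <- if (!is.na(dim_node)) as.integer(num_arr(dim_node))
       else if (all(abs(coords[, 3L]) < 1e-12)) 2L else 3L
  s_node <- xml2::xml_find_first(
    doc, ".//FieldData/DataArray[@Name='CurvatureLimit']")
  ep_node <- xml2::xml_find_first(
    doc, ".//FieldData/DataArray[@Name='Endpoints']")
  ep <- if (!is.na(ep_node)) as.integer(num_arr(ep_node)) + 1L else NULL
  pts <- coords[, seq_len(N), drop = FALSE]
  centerline_model(pts, radii, polylines = polylines,
                   start_index = ep[1L], goal_index = ep[2L],
                   curvature_limit = if (is.na(s_node)) NULL else num_arr(s_node))
}

write_centerlines_vtp <- function(model, path) {
  pts3 <- cbind(model$points,
                matrix(0, nrow(model$points), 3L - model$N))
  fmt <- function(x) paste(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                           collapse = " ")
  conn <- unlist(model$polylines) - 1L
  offs <- cumsum(vapply(model$polylines, length, integer(1)))
  doc <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    '  <PolyData>\n',
    '    <FieldData>\n',
    '      <DataArray type="Int32" Name="Dimensionality" NumberOfTuples="1" format="ascii">',
    model$N, '</DataArray>\n',
    if (!is.null(model$curvature_limit)) paste0(
      '      <DataArray type="Float64" Name="CurvatureLimit" NumberOfTuples="1" format="ascii">',
      fmt(model$curvature_limit), '</DataArray>\n') else "",
    if (!is.null(model$start_index) && !is.null(model$goal_index)) paste0(
      '      <DataArray type="Int64" Name="Endpoints" NumberOfTuples="2" format="ascii">',
      model$start_index - 1L, ' ', model$goal_index - 1L, '</DataArray>\n') else "",
    '    </FieldData>\n',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="%d" NumberOfStrips="0" NumberOfPolys="0">\n',
            nrow(model$points), length(model$polylines)),
    '      <PointData Scalars="MaximumInscribedSphereRadius">\n',
    '        <DataArray type="Float64" Name="MaximumInscribedSphereRadius" NumberOfComponents="1" format="ascii">\n          ',
    fmt(model$radii), '\n        </DataArray>\n',
    '      </PointData>\n',
    '      <Points>\n',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n          ',
    fmt(as.vector(t(pts3))), '\n        </DataArray>\n',
    '      </Points>\n',
    '      <Lines>\n',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">\n          ',
    paste(conn, collapse = " "), '\n        </DataArray>\n',
    '        <DataArray type="Int64" Name="offsets" format="ascii">\n          ',
    paste(offs, collapse = " "), '\n        </DataArray>\n',
    '      </Lines>\n',
    '    </Piece>\n',
    '  </PolyData>\n',
    '</VTKFile>\n')
  writeLines(doc, path)
}
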