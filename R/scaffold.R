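#' Scaffold specification
#'
#' Describes one hexagonal microscaffold: a regular lattice (horizontal
#' dimension `D`) or an elongated one (hexagon bounding box `l` by `L`,
#' stretched along the reference axis), either resting on the substrate
#' ("closed") or raised on pillars ("open").  Total height defaults to
#' 7 micrometres including a 3 micrometre pillar.
#'
#' @param shape `"regular"` or `"elongated"`.
#' @param D horizontal dimension (micrometres) of regular hexagons.
#' @param l,L short/long horizontal dimensions (micrometres) of elongated
#'   hexagons; `0 < l <= L`.
#' @param openness `"open"` (on pillars) or `"closed"`.
#' @param total_height,pillar_height structure heights in micrometres.
#' @param reference_axis unit 2D vector: direction of hexagon elongation
#'   (elongated) or perpendicular to one hexagon side (regular).
#' @return An object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(shape = c("regular", "elongated"), D = NULL,
                          l = NULL, L = NULL,
                          openness = c("open", "closed"),
                          total_height = 7, pillar_height = 3,
                          reference_axis = c(1, 0)) {
  shape <- match.arg(shape)
  openness <- match.arg(openness)
  if (shape == "regular") {
    if (is.null(D) || !is.finite(D) || D <= 0)
      stop("regular scaffold needs D > 0")
    l <- L <- D
  } else {
    if (is.null(l) || is.null(L) || !is.finite(l) || !is.finite(L) ||
        l <= 0 || l > L)
      stop("elongated scaffold needs 0 < l <= L")
    D <- NULL
  }
  if (!(pillar_height > 0 && pillar_height < total_height))
    stop("need 0 < pillar_height < total_height")
  nr <- sqrt(sum(reference_axis^2))
  if (!isTRUE(all.equal(nr, 1, tolerance = 1e-8))) {
    if (nr <= 0) stop("reference_axis must be a nonzero 2D vector")
    reference_axis <- reference_axis / nr
  }
  structure(list(shape = shape, D = D, l = l, L = L, openness = openness,
                 total_height = total_height, pillar_height = pillar_height,
                 reference_axis = reference_axis),
            class = "scaffold_spec")
}

#' Parse a structure name like "D8-open" or "l7L14-closed"
#'
#' Regular lattices are written `D<number>-<open|closed>`, elongated ones
#' `l<number>L<number>-<open|closed>` (prefix letters case-insensitive).
#'
#' @param name structure name.
#' @return A [scaffold_spec()].
#' @examples
#' parse_structure_name("D8-open")
#' parse_structure_name("l7L14-closed")
#' @export
parse_structure_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  num <- "([0-9]+(?:\\.[0-9]+)?)"
  m_reg <- regmatches(name, regexec(paste0("^[Dd]", num, "-(open|closed)$"),
                                    name, ignore.case = TRUE))[[1]]
  m_elo <- regmatches(name, regexec(paste0("^[l]", num, "[L]", num,
                                           "-(open|closed)$"),
                                    name, ignore.case = TRUE))[[1]]
  if (length(m_reg)) {
    return(scaffold_spec("regular", D = as.numeric(m_reg[2]),
                         openness = tolower(m_reg[3])))
  }
  if (length(m_elo)) {
    return(scaffold_spec("elongated", l = as.numeric(m_elo[2]),
                         L = as.numeric(m_elo[3]),
                         openness = tolower(m_elo[4])))
  }
  stop("malformed structure name: ", name,
       " (expected D<number>-<open|closed> or l<number>L<number>-<open|closed>)")
}

num_fmt <- function(x) sub("\\.?0+$", "", format(x, nsmall = 1))

#' @export
format.scaffold_spec <- function(x, ...) {
  if (x$shape == "regular") {
    paste0("D", num_fmt(x$D), "-", x$openness)
  } else {
    paste0("l", num_fmt(x$l), "L", num_fmt(x$L), "-", x$openness)
  }
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat("<scaffold_spec> ", format(x), "  height ", x$total_height,
      " um (pillars ", x$pillar_height, " um), axis (",
      paste(signif(x$reference_axis, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Hexagonal pillar lattice for a scaffold
#'
#' Tiles a rectangular extent with the scaffold's hexagon cells and returns
#' pillar positions (the hexagon vertices) together with the cell polygons.
#' The hexagon family has a bounding box `l` by `L` along the reference
#' axis; regular lattices use `l = L = D`.
#'
#' @param spec a [scaffold_spec()].
#' @param extent numeric length-2, extent in micrometres (x, y).
#' @return list with `pillars` (data.frame `x`, `y` in micrometres) and
#'   `cells` (list of 6x2 polygon matrices), plus the generating `spec`.
#'   Cells are only kept if fully inside the extent; an empty lattice
#'   triggers a warning.
#' @export
pillar_lattice <- function(spec, extent) {
  stopifnot(inherits(spec, "scaffold_spec"), length(extent) == 2L,
            all(extent > 0))
  l <- spec$l; L <- spec$L
  # canonical hexagon, bounding box l x L, long axis along +x
  hexagon <- cbind(x = c(-L / 2, -L / 4, L / 4, L / 2, L / 4, -L / 4),
                   y = c(0, -l / 2, -l / 2, 0, l / 2, l / 2))
  ax <- spec$reference_axis
  rot <- rbind(c(ax[1], -ax[2]), c(ax[2], ax[1]))
  # centres tile with steps (3L/4, l/2): staggered columns
  diag_ext <- sqrt(sum(extent^2))
  ni <- ceiling(diag_ext / (0.75 * L)) + 2L
  nj <- ceiling(diag_ext / (0.5 * l)) + 2L
  cells <- list()
  for (i in seq(-ni, ni)) {
    for (j in seq(-nj, nj)) {
      if ((i + j) %% 2 != 0) next
      ctr <- c(i * 0.75 * L, j * 0.5 * l)
      poly <- sweep(hexagon, 2L, ctr, `+`) %*% t(rot)
      poly <- sweep(poly, 2L, extent / 2, `+`)   # lattice centred on extent
      if (all(poly[, 1] >= 0 & poly[, 1] <= extent[1] &
              poly[, 2] >= 0 & poly[, 2] <= extent[2]))
        cells[[length(cells) + 1L]] <- poly
    }
  }
  if (length(cells) == 0L) {
    warning("extent smaller than one hexagon cell: empty lattice")
    pillars <- data.frame(x = numeric(0), y = numeric(0))
  } else {
    verts <- do.call(rbind, cells)
    verts <- round(verts, 9)
    pillars <- unique(data.frame(x = verts[, 1], y = verts[, 2]))
    pillars <- pillars[order(pillars$x, pillars$y), ]
    rownames(pillars) <- NULL
  }
  list(pillars = pillars, cells = cells, spec = spec)
}
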