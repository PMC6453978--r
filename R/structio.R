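## structio: periodic-geometry kernel plus CIF/XYZ/PDB structure and
## trajectory I/O and nucleobase role assignment.

#' Lower-triangular cell matrix
#'
#' Rows are the lattice vectors a, b, c expressed in the Cartesian frame
#' where a lies along x and b lies in the xy plane (the standard
#' crystallographic lower-triangular convention). Fractional coordinates f
#' map to Cartesian as `f %*% cellMatrix(cell)`.
#'
#' @param cell a [UnitCell-class].
#' @return 3 x 3 numeric matrix, Angstrom.
#' @examples
#' cellMatrix(UnitCell(10, 10, 10))
#' @export
cellMatrix <- function(cell) {
  al <- cell@alpha * pi / 180
  be <- cell@beta * pi / 180
  ga <- cell@gamma * pi / 180
  bx <- cell@b * cos(ga); by <- cell@b * sin(ga)
  cx <- cell@c * cos(be)
  cy <- cell@c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(cell@c^2 - cx^2 - cy^2)
  matrix(c(cell@a, 0, 0,
           bx, by, 0,
           cx, cy, cz), nrow = 3, byrow = TRUE)
}

#' Fractional to Cartesian conversion
#' @param frac n x 3 matrix (or length-3 vector) of fractional coordinates.
#' @param cell a [UnitCell-class].
#' @return n x 3 matrix of Cartesian coordinates, Angstrom.
#' @export
fractionalToCartesian <- function(frac, cell) {
  f <- if (is.null(dim(frac))) matrix(frac, ncol = 3) else as.matrix(frac)
  f %*% cellMatrix(cell)
}

#' Cartesian to fractional conversion
#' @param cart n x 3 matrix (or length-3 vector) of Cartesian coordinates.
#' @param cell a [UnitCell-class].
#' @return n x 3 matrix of fractional coordinates.
#' @export
cartesianToFractional <- function(cart, cell) {
  p <- if (is.null(dim(cart))) matrix(cart, ncol = 3) else as.matrix(cart)
  p %*% solve(cellMatrix(cell))
}

#' Unit-cell volume
#'
#' General triclinic volume \eqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta
#' - \cos^2\gamma + 2\cos\alpha\cos\beta\cos\gamma}}; reduces to
#' \eqn{abc} for an orthorhombic cell.
#'
#' @param cell a [UnitCell-class].
#' @return volume in cubic Angstrom.
#' @examples
#' cellVolume(UnitCell(10.7402, 30.6236, 42.6282))  # 14020.6
#' @export
cellVolume <- function(cell) {
  ar <- c(cell@alpha, cell@beta, cell@gamma) * pi / 180
  cs <- cos(ar)
  cell@a * cell@b * cell@c * sqrt(1 - sum(cs^2) + 2 * prod(cs))
}

#' Minimum-image distance under periodic boundaries
#'
#' Shortest distance between two points over lattice translations: the
#' fractional displacement is wrapped to the central image and a +/-1 image
#' search is performed along each periodic axis (adequate for cutoffs well
#' below half the shortest cell vector, the regime every criterion in this
#' package operates in). Non-periodic axes are left unwrapped.
#'
#' @param p,q length-3 Cartesian points, Angstrom.
#' @param cell a [UnitCell-class].
#' @param periodic logical length-3 per-axis periodicity.
#' @return distance in Angstrom.
#' @examples
#' cube <- UnitCell(10, 10, 10)
#' minimumImageDistance(c(1, 0, 0), c(9, 0, 0), cube)  # 2
#' @export
minimumImageDistance <- function(p, q, cell, periodic = c(TRUE, TRUE, TRUE)) {
  sqrt(sum(minimumImageVector(p, q, cell, periodic)^2))
}

#' Minimum-image displacement vector (q - p, nearest image)
#' @inheritParams minimumImageDistance
#' @return length-3 Cartesian displacement, Angstrom.
#' @export
minimumImageVector <- function(p, q, cell, periodic = c(TRUE, TRUE, TRUE)) {
  M <- cellMatrix(cell)
  df <- as.numeric((q - p) %*% solve(M))
  df[periodic] <- df[periodic] - round(df[periodic])
  shifts <- as.matrix(expand.grid(
    if (periodic[1]) -1:1 else 0,
    if (periodic[2]) -1:1 else 0,
    if (periodic[3]) -1:1 else 0))
  cand <- sweep(shifts, 2, df, "+") %*% M
  d2 <- rowSums(cand^2)
  cand[which.min(d2), ]
}

## ---- CIF ------------------------------------------------------------------

.cif_num <- function(x) as.numeric(sub("\\(.*\\)", "", x))

.parse_symop <- function(op) {
  op <- tolower(gsub("[ ']", "", op))
  parts <- strsplit(op, ",")[[1]]
  if (length(parts) != 3L) stop("malformed symmetry operator: ", op)
  if (grepl("[^xyz0-9+*/.-]", paste(parts, collapse = "")))
    stop("malformed symmetry operator: ", op)
  evalc <- function(expr, x, y, z) eval(parse(text = expr),
                                        list(x = x, y = y, z = z))
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    t[i] <- evalc(parts[i], 0, 0, 0)
    R[i, 1] <- evalc(parts[i], 1, 0, 0) - t[i]
    R[i, 2] <- evalc(parts[i], 0, 1, 0) - t[i]
    R[i, 3] <- evalc(parts[i], 0, 0, 1) - t[i]
  }
  list(R = R, t = t)
}

.element_from_label <- function(label) {
  sym <- sub("^([A-Za-z]{1,2}).*$", "\\1", label)
  two <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, 2)))
  one <- toupper(substr(sym, 1, 1))
  ifelse(nchar(sym) > 1 & .known_element(two), two, one)
}

## Tokenize a CIF loop data line (handles quoted fields).
.cif_tokens <- function(line) {
  toks <- regmatches(line,
    gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

.read_cif <- function(path, radiusOverride = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  get_item <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^\\s*", tag, "\\s+"), "", hit[1])
  }
  cellpar <- vapply(c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                      "_cell_angle_alpha", "_cell_angle_beta",
                      "_cell_angle_gamma"),
                    function(t) .cif_num(get_item(t)), numeric(1))
  if (anyNA(cellpar))
    stop("CIF '", path, "' is missing cell parameters")
  cell <- UnitCell(cellpar[1], cellpar[2], cellpar[3],
                   cellpar[4], cellpar[5], cellpar[6])

  ## locate loops: a loop_ line followed by tag lines then data lines
  loops <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      tags <- character(0); j <- i + 1L
      while (j <= length(lines) && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, sub("^\\s*(\\S+).*$", "\\1", lines[j])); j <- j + 1L
      }
      rows <- list()
      while (j <= length(lines) && !grepl("^\\s*(loop_|_|data_)", lines[j]) &&
             !grepl("^\\s*$", lines[j])) {
        rows[[length(rows) + 1L]] <- .cif_tokens(lines[j]); j <- j + 1L
      }
      loops[[length(loops) + 1L]] <- list(tags = tags, rows = rows)
      i <- j
    } else i <- i + 1L
  }

  symops <- list(list(R = diag(3), t = numeric(3)))
  atoms <- NULL
  for (lp in loops) {
    if (any(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                  lp$tags))) {
      k <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                lp$tags)[1]
      ops <- vapply(lp$rows, function(r) r[min(k, length(r))], character(1))
      symops <- lapply(ops, .parse_symop)
    }
    if (any(lp$tags == "_atom_site_fract_x")) atoms <- lp
  }
  if (is.null(atoms) || !length(atoms$rows))
    stop("CIF format error in '", path, "': no _atom_site_ loop with ",
         "fractional coordinates found")
  tagidx <- function(t) match(t, atoms$tags)
  need <- c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
  if (anyNA(vapply(need, tagidx, integer(1))))
    stop("CIF format error in '", path, "': incomplete fractional coordinates")
  bad <- which(vapply(atoms$rows, length, integer(1)) < length(atoms$tags))
  if (length(bad))
    stop("CIF format error in '", path, "': short atom_site row ", bad[1])
  tab <- do.call(rbind, atoms$rows)
  frac <- cbind(.cif_num(tab[, tagidx("_atom_site_fract_x")]),
                .cif_num(tab[, tagidx("_atom_site_fract_y")]),
                .cif_num(tab[, tagidx("_atom_site_fract_z")]))
  labels <- if (!is.na(tagidx("_atom_site_label")))
    tab[, tagidx("_atom_site_label")] else paste0("X", seq_len(nrow(tab)))
  elements <- if (!is.na(tagidx("_atom_site_type_symbol")))
    gsub("[0-9+\\-]", "", tab[, tagidx("_atom_site_type_symbol")])
  else .element_from_label(labels)
  if (!all(.known_element(elements)))
    stop("unknown element symbol(s) in '", path, "': ",
         paste(unique(elements[!.known_element(elements)]), collapse = ", "))

  ## P1 expansion: apply every operator, wrap into [0,1), deduplicate
  allfrac <- NULL; allel <- character(0); alllab <- character(0)
  for (op in symops) {
    f <- t(op$R %*% t(frac) + op$t)
    if (length(symops) > 1L) f <- f - floor(f)  # wrap on expansion only
    allfrac <- rbind(allfrac, f)
    allel <- c(allel, elements); alllab <- c(alllab, labels)
  }
  keep <- rep(TRUE, nrow(allfrac))
  if (length(symops) > 1L) {
    key <- apply(round(allfrac * 1e3), 1, paste, collapse = ",")
    keep <- !duplicated(paste(alllab, key))
  }
  PeriodicStructure(cell, allel[keep],
                    fractionalToCartesian(allfrac[keep, , drop = FALSE], cell),
                    labels = alllab[keep], radiusOverride = radiusOverride)
}

.write_cif <- function(structure, path) {
  cell <- structure@cell
  frac <- cartesianToFractional(structure@coords, cell)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("data_structure",
               sprintf("_cell_length_a %.6f", cell@a),
               sprintf("_cell_length_b %.6f", cell@b),
               sprintf("_cell_length_c %.6f", cell@c),
               sprintf("_cell_angle_alpha %.6f", cell@alpha),
               sprintf("_cell_angle_beta %.6f", cell@beta),
               sprintf("_cell_angle_gamma %.6f", cell@gamma),
               "loop_",
               "_atom_site_label",
               "_atom_site_type_symbol",
               "_atom_site_fract_x",
               "_atom_site_fract_y",
               "_atom_site_fract_z"), con)
  writeLines(sprintf("%s %s %.8f %.8f %.8f", structure@labels,
                     structure@elements, frac[, 1], frac[, 2], frac[, 3]), con)
  invisible(path)
}

## ---- XYZ ------------------------------------------------------------------

## Extended-XYZ comment line carries the cell as Lattice="ax ay az bx ..."
.read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); comments <- character(0); elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      stop("XYZ format error in '", path, "' at line ", i,
           ": expected atom count")
    if (n == 0L) stop("empty structure in '", path, "' at line ", i)
    if (i + 1L + n > length(lines))
      stop("XYZ format error in '", path, "': truncated frame at line ", i)
    comments <- c(comments, lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    if (any(vapply(toks, length, integer(1)) < 4L))
      stop("XYZ format error in '", path, "': short atom line near line ", i)
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(toks, function(t) t[2:4]))),
                  ncol = 3, byrow = TRUE)
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) stop("empty structure in '", path, "'")
  list(frames = frames, elements = elements, comments = comments)
}

.xyz_lattice_comment <- function(cell) {
  M <- cellMatrix(cell)
  sprintf('Lattice="%s"', paste(sprintf("%.8f", as.numeric(t(M))),
                                collapse = " "))
}

.cell_from_xyz_comment <- function(comment) {
  m <- regmatches(comment, regexpr('Lattice="[^"]+"', comment))
  if (!length(m)) return(NULL)
  v <- as.numeric(strsplit(sub('^Lattice="', "", sub('"$', "", m)),
                           "\\s+")[[1]])
  if (length(v) != 9L || anyNA(v)) return(NULL)
  M <- matrix(v, nrow = 3, byrow = TRUE)
  a <- sqrt(sum(M[1, ]^2)); b <- sqrt(sum(M[2, ]^2)); cc <- sqrt(sum(M[3, ]^2))
  ang <- function(u, v) acos(pmin(1, pmax(-1, sum(u * v) /
                                            sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  UnitCell(a, b, cc, ang(M[2, ], M[3, ]), ang(M[1, ], M[3, ]), ang(M[1, ], M[2, ]))
}

.write_xyz_frames <- function(frames, elements, path, cell = NULL,
                              comments = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    cm <- if (!is.null(comments)) comments[k]
    else if (!is.null(cell)) .xyz_lattice_comment(cell) else ""
    writeLines(c(as.character(nrow(f)), cm), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", elements, f[, 1], f[, 2], f[, 3]),
               con)
  }
  invisible(path)
}

## ---- PDB ------------------------------------------------------------------

.read_pdb_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cell <- NULL
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl)) {
    v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                      substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
    if (!anyNA(v)) cell <- UnitCell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  frames <- list(); elements <- NULL; labels <- NULL
  cur <- NULL; curel <- character(0); curlab <- character(0)
  flush <- function() {
    if (!is.null(cur) && nrow(cur)) {
      frames[[length(frames) + 1L]] <<- cur
      if (is.null(elements)) { elements <<- curel; labels <<- curlab }
    }
    cur <<- NULL; curel <<- character(0); curlab <<- character(0)
  }
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (rec %in% c("ATOM  ", "HETATM")) {
      xyz <- as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                          substr(ln, 47, 54)))
      if (anyNA(xyz)) stop("PDB format error in '", path, "': bad ATOM line")
      el <- trimws(substr(ln, 77, 78))
      if (!nzchar(el)) el <- .element_from_label(trimws(substr(ln, 13, 16)))
      el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
      cur <- rbind(cur, xyz)
      curel <- c(curel, el); curlab <- c(curlab, trimws(substr(ln, 13, 16)))
    } else if (rec == "ENDMDL") flush()
  }
  flush()
  if (!length(frames)) stop("empty structure in '", path, "'")
  if (!all(.known_element(elements)))
    stop("unknown element symbol(s) in '", path, "': ",
         paste(unique(elements[!.known_element(elements)]), collapse = ", "))
  list(frames = frames, elements = elements, labels = labels, cell = cell)
}

.write_pdb_frames <- function(frames, elements, path, cell = NULL,
                              labels = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(cell))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       cell@a, cell@b, cell@c, cell@alpha, cell@beta,
                       cell@gamma), con)
  if (is.null(labels)) labels <- elements
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    f <- frames[[k]]
    writeLines(sprintf(
      "HETATM%5d %-4s MOL A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(f)) %% 100000L, substr(labels, 1, 4),
      f[, 1], f[, 2], f[, 3], elements), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- public I/O -----------------------------------------------------------

.guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("cif", "xyz", "pdb")) ext
  else stop("cannot guess format from extension of '", path, "'")
}

#' Read a periodic structure
#'
#' Reads CIF (cell + fractional coordinates; symmetry operators are expanded
#' to P1), XYZ (extended-XYZ `Lattice="..."` comment carries the cell) or
#' PDB (CRYST1 record). Sites are assigned van der Waals radii from the
#' bundled Bondi table, overridable per element.
#'
#' @param path input file.
#' @param format "cif", "xyz" or "pdb"; guessed from the extension by default.
#' @param radiusOverride named numeric radius overrides ([vdwRadius()]).
#' @return a [PeriodicStructure-class].
#' @export
readStructure <- function(path, format = c("auto", "cif", "xyz", "pdb"),
                          radiusOverride = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (format == "cif") return(.read_cif(path, radiusOverride))
  if (format == "xyz") {
    x <- .read_xyz_frames(path)
    cell <- .cell_from_xyz_comment(x$comments[1])
    if (is.null(cell))
      stop("XYZ '", path, "' carries no Lattice=\"...\" cell; supply one")
    return(PeriodicStructure(cell, x$elements, x$frames[[1]],
                             radiusOverride = radiusOverride))
  }
  x <- .read_pdb_frames(path)
  if (is.null(x$cell)) stop("PDB '", path, "' has no CRYST1 cell record")
  PeriodicStructure(x$cell, x$elements, x$frames[[1]], labels = x$labels,
                    radiusOverride = radiusOverride)
}

#' Write a periodic structure
#' @param structure a [PeriodicStructure-class].
#' @param path output file.
#' @param format "cif", "xyz" or "pdb"; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(structure, path,
                           format = c("auto", "cif", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (format == "cif") return(.write_cif(structure, path))
  if (format == "xyz")
    return(.write_xyz_frames(list(structure@coords), structure@elements, path,
                             cell = structure@cell))
  .write_pdb_frames(list(structure@coords), structure@elements, path,
                    cell = structure@cell, labels = structure@labels)
}

#' Read a multi-frame trajectory
#'
#' Multi-frame XYZ (frame interval from argument; cell from the first
#' frame's `Lattice` comment unless given) or multi-model PDB (cell from
#' CRYST1). The cell is fixed across frames; XYZ input whose per-frame
#' `Lattice` comments disagree is rejected.
#'
#' @param path input file.
#' @param frameInterval frame spacing in ps.
#' @param topology list of [NucleobaseInstance-class] (e.g. from
#'   [assignNucleobases()] or a role-config file).
#' @param cell optional [UnitCell-class] overriding the file's cell.
#' @param format "xyz" or "pdb"; guessed from the extension by default.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, frameInterval, topology = list(),
                           cell = NULL, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (format == "xyz") {
    x <- .read_xyz_frames(path)
    cells <- lapply(x$comments, .cell_from_xyz_comment)
    if (is.null(cell)) cell <- cells[[1]]
    if (is.null(cell))
      stop("XYZ '", path, "' carries no cell; supply `cell`")
    got <- !vapply(cells, is.null, logical(1))
    if (any(got)) {
      ref <- vapply(cells[got], function(cl)
        max(abs(cellMatrix(cl) - cellMatrix(cell))), numeric(1))
      if (any(ref > 1e-6))
        stop("trajectory cell changes between frames; fixed-cell ",
             "(NVT-like) trajectories only")
    }
    return(Trajectory(x$frames, frameInterval, topology, cell,
                      elements = x$elements))
  }
  x <- .read_pdb_frames(path)
  if (is.null(cell)) cell <- x$cell
  if (is.null(cell)) stop("PDB '", path, "' has no CRYST1 cell; supply `cell`")
  Trajectory(x$frames, frameInterval, topology, cell, elements = x$elements)
}

#' Write a trajectory to multi-frame XYZ or multi-model PDB
#' @param trajectory a [Trajectory-class].
#' @param path output file.
#' @param format "xyz" or "pdb"; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  el <- trajectory@elements
  if (!length(el)) el <- rep("C", nrow(trajectory@frames[[1]]))
  if (format == "xyz")
    return(.write_xyz_frames(trajectory@frames, el, path,
                             cell = trajectory@cell))
  .write_pdb_frames(trajectory@frames, el, path, cell = trajectory@cell)
}

## ---- role assignment ------------------------------------------------------

#' Assign nucleobase atom roles from labelled sites
#'
#' Label-based role resolution: each molecule is a group of atom indices;
#' the role config maps, per base kind, role names (conventional nucleobase
#' numbering: adenine N1, N6, ...; thymine N3, O4, C5, C6, ...) to the atom
#' labels carried by the structure or trajectory. Every molecule is either
#' resolved into exactly one [NucleobaseInstance-class] or reported
#' unassigned (error by default).
#'
#' @param labels character vector of atom labels (structure site labels or
#'   trajectory atom labels).
#' @param molecules list of integer vectors: atom indices of each molecule.
#' @param roleConfig list with one entry per molecule id (or a single
#'   template applied to all): `list(baseKind=, roles=c(N1="lab", ...))`.
#'   Role-to-label matching is exact on the molecule's own atoms.
#' @param baseKinds character vector giving each molecule's base kind when
#'   `roleConfig` holds shared per-kind templates
#'   (`list(adenine = c(N1 = "N1", ...), thymine = ...)`).
#' @param onUnassigned "error" or "drop".
#' @return list of [NucleobaseInstance-class].
#' @export
assignNucleobases <- function(labels, molecules, roleConfig,
                              baseKinds = NULL,
                              onUnassigned = c("error", "drop")) {
  onUnassigned <- match.arg(onUnassigned)
  out <- list()
  for (m in seq_along(molecules)) {
    idx <- as.integer(molecules[[m]])
    if (!is.null(baseKinds)) {
      kind <- baseKinds[m]
      roles <- roleConfig[[kind]]
    } else {
      cfg <- roleConfig[[m]]
      kind <- cfg$baseKind
      roles <- cfg$roles
    }
    if (is.null(roles)) {
      if (onUnassigned == "error")
        stop("molecule ", m, ": no role template for base kind '", kind, "'")
      next
    }
    labhere <- labels[idx]
    resolved <- integer(0)
    for (r in names(roles)) {
      hit <- idx[labhere == roles[[r]]]
      if (length(hit) > 1L)
        stop("molecule ", m, ": label '", roles[[r]],
             "' matches several atoms (ambiguous role ", r, ")")
      if (length(hit) == 1L) resolved[r] <- hit
    }
    missing <- setdiff(.REQUIRED_ROLES[[kind]], names(resolved))
    if (length(missing)) {
      if (onUnassigned == "error")
        stop("molecule ", m, " (", kind, "): role ",
             paste(missing, collapse = ", "), " unresolved")
      next
    }
    out[[length(out) + 1L]] <- NucleobaseInstance(kind, m, resolved)
  }
  out
}

#' Write / read a role configuration as JSON
#'
#' The on-disk form records, per molecule, the base kind and the
#' role-to-atom-index map, so a trajectory file plus its role config fully
#' reconstruct the [Trajectory-class] topology.
#'
#' @param topology list of [NucleobaseInstance-class].
#' @param path file path.
#' @return `path` invisibly (write); list of instances (read).
#' @export
writeRoleConfig <- function(topology, path) {
  x <- lapply(topology, function(nb)
    list(baseKind = nb@baseKind, moleculeId = nb@moleculeId,
         roles = as.list(nb@roleMap)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeRoleConfig
#' @export
readRoleConfig <- function(path) {
  x <- jsonlite::read_json(path)
  lapply(x, function(e)
    NucleobaseInstance(e$baseKind, e$moleculeId,
                       stats::setNames(as.integer(unlist(e$roles)),
                                       names(e$roles))))
}
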