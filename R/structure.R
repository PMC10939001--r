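# The atomistic Structure container and (extended) XYZ input/output.

#' Create an atomistic structure
#'
#' The basic container used throughout the package: element symbols, Cartesian
#' coordinates, a periodic cell, a frozen-atom mask and adsorbate/substrate
#' tags.
#'
#' @param symbols character vector of element symbols (length N).
#' @param positions N x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param cell 3 x 3 matrix of lattice vectors (rows), Angstrom.  May be all
#'   zero for an isolated molecule.
#' @param pbc logical length-3 periodicity flags.
#' @param frozen logical length-N mask; frozen atoms never move in relaxation.
#' @param tags character length-N, each `"adsorbate"` or `"substrate"`.
#' @param energy optional total energy (eV) attached to the frame.
#' @param forces optional N x 3 matrix of forces (eV/Angstrom).
#' @param info optional named list of extra metadata.
#' @return object of class `surfbo_structure`.
#' @export
structure_new <- function(symbols, positions,
                          cell = matrix(0, 3, 3),
                          pbc = c(FALSE, FALSE, FALSE),
                          frozen = NULL, tags = NULL,
                          energy = NULL, forces = NULL, info = list()) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions)) || ncol(positions) != 3)
    stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  symbols <- as.character(symbols)
  if (length(symbols) != n) stop("symbols and positions disagree in length")
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  if (is.null(tags)) tags <- rep("adsorbate", n)
  if (length(frozen) != n || length(tags) != n)
    stop("frozen and tags must have one entry per atom")
  if (!all(tags %in% c("adsorbate", "substrate")))
    stop("tags must be 'adsorbate' or 'substrate'")
  cell <- as.matrix(cell)
  stopifnot(all(dim(cell) == c(3, 3)))
  pbc <- as.logical(pbc)
  stopifnot(length(pbc) == 3)
  for (k in which(pbc)) {
    if (sqrt(sum(cell[k, ]^2)) <= 0)
      stop("periodic direction ", k, " has a zero cell vector")
  }
  if (any(pbc) && det(cell) < 0)
    stop("cell must be right-handed")
  if (!is.null(forces)) {
    forces <- as.matrix(forces)
    stopifnot(all(dim(forces) == c(n, 3)))
  }
  obj <- list(symbols = symbols, positions = positions, cell = cell,
              pbc = pbc, frozen = as.logical(frozen), tags = tags,
              energy = energy, forces = forces, info = info)
  class(obj) <- "surfbo_structure"
  obj
}

#' @export
print.surfbo_structure <- function(x, ...) {
  comp <- table(x$symbols)
  cat(sprintf("<surfbo_structure: %d atoms [%s]%s%s>\n",
              n_atoms(x),
              paste0(names(comp), comp, collapse = " "),
              if (any(x$pbc)) " periodic" else "",
              if (!is.null(x$energy)) sprintf(" E=%.4f eV", x$energy) else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `surfbo_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$positions)

#' Combine two structures into one frame
#'
#' Atom order is `a` followed by `b`; cell and periodicity are taken from the
#' periodic partner (or from `a` if neither/both are periodic).
#' @param a,b structures.
#' @return combined `surfbo_structure`.
#' @export
structure_cat <- function(a, b) {
  use <- if (any(b$pbc) && !any(a$pbc)) b else a
  structure_new(c(a$symbols, b$symbols),
                rbind(a$positions, b$positions),
                cell = use$cell, pbc = use$pbc,
                frozen = c(a$frozen, b$frozen),
                tags = c(a$tags, b$tags),
                info = use$info)
}

#' Extract a subset of atoms
#' @param s a structure.
#' @param idx integer or logical atom index.
#' @return new `surfbo_structure` with the selected atoms.
#' @export
structure_subset <- function(s, idx) {
  structure_new(s$symbols[idx], s$positions[idx, , drop = FALSE],
                cell = s$cell, pbc = s$pbc,
                frozen = s$frozen[idx], tags = s$tags[idx],
                forces = if (!is.null(s$forces)) s$forces[idx, , drop = FALSE],
                info = s$info)
}

#' Geometric center of (a subset of) a structure
#' @param s a structure.
#' @param tags optional tag filter, e.g. `"adsorbate"`.
#' @return length-3 centroid.
#' @export
geometric_center <- function(s, tags = NULL) {
  idx <- if (is.null(tags)) seq_len(n_atoms(s)) else which(s$tags %in% tags)
  colMeans(s$positions[idx, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Extended XYZ

fmt_num <- function(x) formatC(x, format = "f", digits = 8)

#' Write structures as (extended) XYZ
#'
#' Writes one or more frames in the extended XYZ dialect:
#' `Lattice="ax ay az bx by bz cx cy cz"`,
#' `Properties=species:S:1:pos:R:3:tags:S:1:frozen:I:1[:forces:R:3]` and an
#' optional `energy=<eV>` entry on the comment line.
#'
#' @param s a `surfbo_structure` or list of them.
#' @param path output file path.
#' @param append append frames to an existing file.
#' @export
write_xyz <- function(s, path, append = FALSE) {
  frames <- if (inherits(s, "surfbo_structure")) list(s) else s
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- n_atoms(fr)
    props <- "Properties=species:S:1:pos:R:3:tags:S:1:frozen:I:1"
    cols <- cbind(fr$symbols,
                  apply(fr$positions, 2, fmt_num),
                  fr$tags, as.integer(fr$frozen))
    if (!is.null(fr$forces)) {
      props <- paste0(props, ":forces:R:3")
      cols <- cbind(cols, apply(fr$forces, 2, formatC,
                                format = "e", digits = 12))
    }
    lat <- sprintf('Lattice="%s"', paste(fmt_num(t(fr$cell)), collapse = " "))
    pbc <- sprintf('pbc="%s"', paste(ifelse(fr$pbc, "T", "F"), collapse = " "))
    comment <- paste(lat, props, pbc)
    if (!is.null(fr$energy))
      comment <- paste(comment, sprintf("energy=%.14e", fr$energy))
    writeLines(as.character(n), con)
    writeLines(comment, con)
    writeLines(apply(cols, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

parse_kv <- function(line) {
  # key=value pairs where value may be double-quoted
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (i in seq_along(m)) {
    tok <- substr(line, m[i], m[i] + attr(m, "match.length")[i] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}

#' Read (extended) XYZ frames
#'
#' Accepts both plain XYZ and the extended dialect written by [write_xyz()].
#'
#' @param path input file path.
#' @return list of `surfbo_structure` frames (a single structure if the file
#'   holds one frame and `simplify` is `TRUE`).
#' @param simplify return the bare structure for single-frame files.
#' @export
read_xyz <- function(path, simplify = TRUE) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    comment <- lines[i + 1L]
    kv <- parse_kv(comment)
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    symbols <- vapply(toks, `[`, "", 1L)
    pos <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    tags <- NULL; frozen <- NULL; forces <- NULL
    if (!is.null(kv$Properties)) {
      fields <- strsplit(kv$Properties, ":")[[1]]
      col <- 1L
      for (k in seq(1, length(fields), by = 3)) {
        nm <- fields[k]; width <- as.integer(fields[k + 2])
        if (nm == "tags") tags <- vapply(toks, `[`, "", col)
        if (nm == "frozen")
          frozen <- as.logical(as.integer(vapply(toks, `[`, "", col)))
        if (nm == "forces")
          forces <- t(vapply(toks, function(t)
            as.numeric(t[col:(col + 2)]), numeric(3)))
        col <- col + width
      }
    }
    cell <- matrix(0, 3, 3)
    pbc <- c(FALSE, FALSE, FALSE)
    if (!is.null(kv$Lattice)) {
      cell <- matrix(as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]]),
                     3, 3, byrow = TRUE)
    }
    if (!is.null(kv$pbc)) {
      pbc <- toupper(strsplit(trimws(kv$pbc), "\\s+")[[1]]) %in% "T"
    } else if (!is.null(kv$Lattice)) {
      pbc <- rowSums(cell^2) > 0
    }
    energy <- if (!is.null(kv$energy)) as.numeric(kv$energy) else NULL
    frames[[length(frames) + 1L]] <-
      structure_new(symbols, pos, cell = cell, pbc = pbc,
                    frozen = frozen, tags = tags,
                    energy = energy, forces = forces)
    i <- i + 2L + n
  }
  if (simplify && length(frames) == 1L) frames[[1]] else frames
}
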