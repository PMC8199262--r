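#' Read a single-cell Hi-C contact list
#'
#' Parses a whitespace/tab-delimited contact list with at least four columns
#' (`chromA posA chromB posB`; extra columns ignored, lines starting with `#`
#' skipped) and keeps only intra-chromosomal records for one chromosome.
#' This is the dialect used by cleaned single-cell Hi-C contact files on GEO.
#'
#' @param path Path to the contact list file.
#' @param chrom Chromosome name to keep; only records with both ends on this
#'   chromosome are returned.
#' @return A data.frame with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`
#'   (positions are 1-based genomic coordinates in bp).
#' @export
read_contacts <- function(path, chrom) {
  if (!file.exists(path)) {
    stop("cannot read contact file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("no contacts found in ", path, " for chromosome ", chrom)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  n_bad <- 0L
  recs <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 4L) {
      n_bad <- n_bad + 1L
      next
    }
    pa <- suppressWarnings(as.numeric(f[2L]))
    pb <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(pa) || is.na(pb) || pa < 1 || pb < 1) {
      n_bad <- n_bad + 1L
      next
    }
    recs[[k]] <- data.frame(chrom_a = f[1L], pos_a = pa,
                            chrom_b = f[3L], pos_b = pb,
                            stringsAsFactors = FALSE)
  }
  if (n_bad > 0L) {
    message(n_bad, " malformed line(s) skipped in ", path)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    stop("no contacts found in ", path, " for chromosome ", chrom)
  }
  df <- do.call(rbind, recs)
  df <- df[df$chrom_a == chrom & df$chrom_b == chrom, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no intra-chromosomal contacts for chromosome ", chrom, " in ", path)
  }
  rownames(df) <- NULL
  df
}

#' Bin a contact list into a binary bead-pair contact matrix
#'
#' Genomic positions are assigned to beads by 0-based half-open bins: bead
#' `k` covers `[k * resolution, (k + 1) * resolution)`. Each surviving record
#' sets the corresponding symmetric pair of entries to 1; duplicates collapse
#' (the matrix is binary: 1 means at least one contact was observed) and
#' self-contacts (both ends in the same bead) are dropped and counted.
#'
#' @param records Data.frame as returned by [read_contacts()].
#' @param resolution Bead size in bp (e.g. 500000 or 50000).
#' @param chrom_length Chromosome length in bp; the bead count is
#'   `ceiling(chrom_length / resolution)`.
#' @param chrom Chromosome name stored in the result (default taken from the
#'   records).
#' @return A `contact_matrix` object: list with `values` (symmetric l x l
#'   0/1 integer matrix, zero diagonal), `resolution`, `chrom`, `n_beads`.
#' @export
bin_to_matrix <- function(records, resolution, chrom_length,
                          chrom = records$chrom_a[1L]) {
  stopifnot(resolution > 0, chrom_length > 0)
  if (any(records$pos_a > chrom_length | records$pos_b > chrom_length)) {
    bad <- which(records$pos_a > chrom_length | records$pos_b > chrom_length)[1L]
    stop("contact position exceeds chromosome length ", chrom_length,
         " at record ", bad, ": pos_a=", records$pos_a[bad],
         " pos_b=", records$pos_b[bad])
  }
  l <- as.integer(ceiling(chrom_length / resolution))
  i <- floor((records$pos_a - 1) / resolution)
  j <- floor((records$pos_b - 1) / resolution)
  self <- i == j
  if (any(self)) {
    message(sum(self), " self-contact(s) removed during binning")
  }
  i <- i[!self]
  j <- j[!self]
  values <- matrix(0L, l, l)
  if (length(i) > 0L) {
    values[cbind(i + 1L, j + 1L)] <- 1L
    values[cbind(j + 1L, i + 1L)] <- 1L
  }
  contact_matrix(values, resolution = resolution, chrom = chrom)
}

#' Construct a contact_matrix object
#'
#' @param values Symmetric 0/1 square matrix with zero diagonal.
#' @param resolution Bead size in bp.
#' @param chrom Chromosome name.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(values, resolution, chrom = "chr") {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  stopifnot(nrow(values) == ncol(values),
            all(values %in% c(0L, 1L)),
            all(diag(values) == 0L),
            isTRUE(all.equal(values, t(values))))
  structure(list(values = values, resolution = resolution, chrom = chrom,
                 n_beads = nrow(values)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$n_beads, "beads @", x$resolution, "bp,",
      sum(x$values[upper.tri(x$values)]), "contacts (", x$chrom, ")\n")
  invisible(x)
}

#' Construct a lattice_conformation object
#'
#' A chromosome conformation on an integer cubic lattice: one 3D integer
#' coordinate per bead, beads in genomic order, all sites distinct, every
#' component in `[0, lattice_side)`.
#'
#' @param coords Integer matrix with l rows and 3 columns.
#' @param lattice_side Side length of the cubic lattice (default `5 * l`).
#' @param resolution Bead size in bp.
#' @return A `lattice_conformation` object.
#' @export
lattice_conformation <- function(coords, lattice_side = 5L * nrow(coords),
                                 resolution = NA_real_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L,
            all(coords >= 0L), all(coords < lattice_side))
  if (anyDuplicated(coords)) {
    stop("two beads share a lattice site")
  }
  structure(list(coords = coords, lattice_side = as.integer(lattice_side),
                 resolution = resolution),
            class = "lattice_conformation")
}

#' @export
print.lattice_conformation <- function(x, ...) {
  cat("lattice_conformation:", nrow(x$coords), "beads, lattice side",
      x$lattice_side, "\n")
  invisible(x)
}

coords_of <- function(conf) {
  if (inherits(conf, "lattice_conformation")) conf$coords else as.matrix(conf)
}

#' Write a conformation to disk
#'
#' `pdb` writes one CA pseudo-atom per bead (residue number = bead index + 1,
#' single chain, lattice units written verbatim into the coordinate fields)
#' for compatibility with common 3D-genome viewers. `csv` writes columns
#' `bead_index` (0-based), `genomic_start` (bp), `x`, `y`, `z`; a CSV round
#' trip through [read_structure_csv()] restores coordinates exactly.
#'
#' @param conf A `lattice_conformation`.
#' @param path Output file path.
#' @param format `"pdb"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(conf, path, format = c("csv", "pdb")) {
  format <- match.arg(format)
  xyz <- coords_of(conf)
  l <- nrow(xyz)
  if (format == "csv") {
    res <- if (is.na(conf$resolution)) 1 else conf$resolution
    df <- data.frame(bead_index = seq_len(l) - 1L,
                     genomic_start = (seq_len(l) - 1L) * res,
                     x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- sprintf(
      "ATOM  %5d  CA  BED A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(l), seq_len(l),
      as.numeric(xyz[, 1L]), as.numeric(xyz[, 2L]), as.numeric(xyz[, 3L]))
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}

#' Read a conformation written by [write_structure()] in CSV format
#'
#' @param path CSV file with columns `bead_index`, `genomic_start`, `x`, `y`, `z`.
#' @param lattice_side Lattice side; defaults to `5 * l`.
#' @return A `lattice_conformation`.
#' @export
read_structure_csv <- function(path, lattice_side = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("bead_index", "x", "y", "z") %in% names(df)))
  df <- df[order(df$bead_index), , drop = FALSE]
  res <- if ("genomic_start" %in% names(df) && nrow(df) > 1L) {
    df$genomic_start[2L] - df$genomic_start[1L]
  } else NA_real_
  coords <- as.matrix(df[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  if (is.null(lattice_side)) lattice_side <- 5L * nrow(coords)
  lattice_conformation(coords, lattice_side = lattice_side, resolution = res)
}
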