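#' Read a PDB file into an AtomicSystem
#'
#' Parses standard fixed-column ATOM/HETATM records (via bio3d) into an
#' [AtomicSystem].  Residue indices are taken from the PDB (1-based) and
#' chains are preserved.  Elements are taken from the element column
#' when present and otherwise inferred from the atom name.  Fragment
#' exclusion-group membership is recovered from segment labels of the
#' form `Gnnn` written by [writePDB]; all other atoms are host atoms
#' (fragment id 0).
#'
#' A PDB file carries no bonded topology: systems read from disk have
#' empty bonded-term tables.  Topologies originate from the fixture
#' generators and the fragment builders.
#'
#' @param path path to a PDB file
#' @return an [AtomicSystem]
#' @seealso [writePDB()]
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(recs)) stop("no ATOM/HETATM records in ", path)
  for (ln in which(recs)) {
    for (fld in list(c(31L, 38L, "x"), c(39L, 46L, "y"), c(47L, 54L, "z"))) {
      raw <- substr(lines[ln], as.integer(fld[1L]), as.integer(fld[2L]))
      if (is.na(suppressWarnings(as.numeric(raw))))
        stop(sprintf("malformed %s-coordinate field at line %d: '%s'",
                     fld[3L], ln, trimws(raw)))
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  n <- nrow(at)
  elesy <- trimws(at$elesy)
  element <- vapply(seq_len(n), function(i) {
    if (!is.na(elesy[i]) && nzchar(elesy[i]) &&
        toupper(elesy[i]) %in% .elementTable$element)
      toupper(elesy[i])
    else .inferElement(at$elety[i], at$resid[i])
  }, character(1L))
  segid <- trimws(at$segid)
  segid[is.na(segid)] <- ""
  fragId <- ifelse(grepl("^G[0-9]+$", segid),
                   as.integer(sub("^G", "", segid)), 0L)
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- .atomRows(serial = at$eleno, name = trimws(at$elety),
                     element = element, resid = at$resno,
                     resname = trimws(at$resid), chain = chain,
                     segid = segid, charge = 0, fragmentId = fragId)
  pos <- cbind(at$x, at$y, at$z)
  .makeSystem(atoms = atoms, positions = pos)
}

#' Write an AtomicSystem to a PDB file
#'
#' Emits fixed-column ATOM records with `%8.3f` coordinates.  Fragment
#' atoms carry segment labels `Gnnn` encoding their exclusion group so
#' that copies remain distinguishable in a viewer and survive a round
#' trip through [readPDB] even when the group count exceeds the chain
#' alphabet.
#'
#' @param system an [AtomicSystem]
#' @param path output path
#' @return `path`, invisibly
#' @export
writePDB <- function(system, path) {
  stopifnot(is(system, "AtomicSystem"))
  a <- system@atoms
  if (nrow(a) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  if (any(abs(system@positions) >= 1e4))
    stop("coordinate magnitude >= 10^4 A cannot be represented in ",
         "fixed-column PDB format")
  segid <- ifelse(a$fragmentId > 0L, sprintf("G%d", a$fragmentId), a$segid)
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(system@positions)),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resid, resid = a$resname,
                   eleno = a$serial, elety = a$name,
                   chain = ifelse(is.na(a$chain) | a$chain == "",
                                  " ", a$chain),
                   elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  ## patch segment labels into columns 73-76 (not emitted by the writer)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  lines[rec] <- vapply(seq_len(sum(rec)), function(k) {
    ln <- lines[rec][k]
    ln <- formatC(ln, width = -80)
    paste0(substr(ln, 1L, 72L), formatC(segid[k], width = -4),
           substr(ln, 77L, nchar(ln)))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
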