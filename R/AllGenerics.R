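#' Number of atoms in a system
#' @param x an [AtomicSystem]
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "AtomicSystem", function(x) nrow(x@atoms))

#' Atom table accessor
#' @param x an [AtomicSystem]
#' @return the atom data.frame
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "AtomicSystem", function(x) x@atoms)

#' Coordinate accessors
#' @param x an [AtomicSystem] or [SimulationState]
#' @param value replacement n x 3 coordinate matrix (Angstrom)
#' @return `positions` returns the n x 3 coordinate matrix.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname positions
#' @export
setMethod("positions", "AtomicSystem", function(x) x@positions)

#' @rdname positions
#' @export
setMethod("positions", "SimulationState", function(x) x@positions)

#' @rdname positions
#' @export
setGeneric("positions<-", function(x, value) standardGeneric("positions<-"))

#' @rdname positions
#' @export
setMethod("positions<-", "AtomicSystem", function(x, value) {
  stopifnot(is.matrix(value), identical(dim(value), dim(x@positions)))
  x@positions <- value
  validObject(x)
  x
})

#' Histogram accessors
#'
#' `histValues` returns the per-bin densities (1/Angstrom), `binWidth`
#' the bin width and `binCenters` the bin-centre grid `n * binWidth`.
#' @param x a [HistogramTable]
#' @return numeric vector or scalar as described
#' @export
setGeneric("histValues", function(x) standardGeneric("histValues"))

#' @rdname histValues
#' @export
setMethod("histValues", "HistogramTable", function(x) x@values)

#' @rdname histValues
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname histValues
#' @export
setMethod("binWidth", "HistogramTable", function(x) x@binWidth)

#' @rdname histValues
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname histValues
#' @export
setMethod("binCenters", "HistogramTable",
          function(x) seq_along(x@values) * x@binWidth)

#' Restraint term table accessor
#' @param x a [RestraintSet]
#' @return the term data.frame
#' @export
setGeneric("restraintTerms", function(x) standardGeneric("restraintTerms"))

#' @rdname restraintTerms
#' @export
setMethod("restraintTerms", "RestraintSet", function(x) x@terms)

#' Fragment accessors
#' @param x a [MolecularFragment] or [CopyEnsemble]
#' @return `fragmentAtoms`: integer atom indices; `exclusionGroup`:
#'   group id(s); `interactionScale`: environment scale;
#'   `probeAtoms`: probe atom indices; `copies`: list of fragments.
#' @export
setGeneric("fragmentAtoms", function(x) standardGeneric("fragmentAtoms"))

#' @rdname fragmentAtoms
#' @export
setMethod("fragmentAtoms", "MolecularFragment", function(x) x@atomIndices)

#' @rdname fragmentAtoms
#' @export
setGeneric("exclusionGroup", function(x) standardGeneric("exclusionGroup"))

#' @rdname fragmentAtoms
#' @export
setMethod("exclusionGroup", "MolecularFragment", function(x) x@exclusionGroup)

#' @rdname fragmentAtoms
#' @export
setGeneric("interactionScale", function(x) standardGeneric("interactionScale"))

#' @rdname fragmentAtoms
#' @export
setMethod("interactionScale", "MolecularFragment", function(x) x@scale)

#' @rdname fragmentAtoms
#' @export
setGeneric("probeAtoms", function(x) standardGeneric("probeAtoms"))

#' @rdname fragmentAtoms
#' @export
setMethod("probeAtoms", "CopyEnsemble", function(x) x@probeAtoms)

#' @rdname fragmentAtoms
#' @export
setMethod("probeAtoms", "MolecularFragment", function(x) x@probeAtom)

#' @rdname fragmentAtoms
#' @export
setGeneric("copies", function(x) standardGeneric("copies"))

#' @rdname fragmentAtoms
#' @export
setMethod("copies", "CopyEnsemble", function(x) x@copies)

setMethod("show", "AtomicSystem", function(object) {
  a <- object@atoms
  nFrag <- if (nrow(a)) length(setdiff(unique(a$fragmentId), 0L)) else 0L
  cat(sprintf("AtomicSystem: %d atoms, %d residues, %d chain(s)\n",
              nrow(a),
              if (nrow(a)) length(unique(paste(a$chain, a$resid))) else 0L,
              if (nrow(a)) length(unique(a$chain)) else 0L))
  cat(sprintf("  bonded terms: %d bonds, %d angles, %d dihedrals\n",
              nrow(object@bonds), nrow(object@angles),
              nrow(object@dihedrals)))
  cat(sprintf("  fragment exclusion groups: %d\n", nFrag))
  invisible(object)
})

setMethod("show", "MolecularFragment", function(object) {
  cat(sprintf(
    "MolecularFragment (%s): %d atoms at site(s) %s, group %d, scale %.4g\n",
    object@kind, length(object@atomIndices),
    paste(object@sites, collapse = "/"),
    object@exclusionGroup, object@scale))
  invisible(object)
})

setMethod("show", "CopyEnsemble", function(object) {
  cat(sprintf("CopyEnsemble (%s): site %d, %d copies, scale 1/%d\n",
              object@kind, object@site, length(object@copies),
              length(object@copies)))
  invisible(object)
})

setMethod("show", "HistogramTable", function(object) {
  v <- object@values
  cat(sprintf(
    "HistogramTable: %d bins, dr = %g A, mean distance %.2f A\n",
    length(v), object@binWidth,
    sum(seq_along(v) * object@binWidth * v) * object@binWidth))
  invisible(object)
})

setMethod("show", "RestraintSet", function(object) {
  tab <- table(object@terms$kind)
  cat(sprintf("RestraintSet: %d terms (%s)\n", nrow(object@terms),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(object)
})
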