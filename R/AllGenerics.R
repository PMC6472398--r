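## Accessor generics.  Slots are never touched directly outside the package.

#' @rdname accessors
#' @param x an object from this package.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname accessors
#' @export
setGeneric("cdsSequences", function(x) standardGeneric("cdsSequences"))

#' @rdname accessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname accessors
#' @export
setGeneric("anchorType", function(x) standardGeneric("anchorType"))

#' @rdname accessors
#' @export
setGeneric("multimapFraction", function(x) standardGeneric("multimapFraction"))

#' @rdname accessors
#' @export
setGeneric("offsetRows", function(x) standardGeneric("offsetRows"))

#' @rdname accessors
#' @export
setGeneric("sfPmf", function(x) standardGeneric("sfPmf"))

#' @rdname accessors
#' @export
setGeneric("asiteValues", function(x) standardGeneric("asiteValues"))

#' @rdname accessors
#' @export
setGeneric("asiteMethod", function(x) standardGeneric("asiteMethod"))

#' Accessors for riboAsite classes
#'
#' `geneIds` returns gene identifiers; `geneInfo` the per-gene geometry
#' table; `cdsSequences` the CDS [Biostrings::DNAStringSet];
#' `profileCounts` the sparse count table of a [RiboProfileSet-class];
#' `anchorType` its anchor; `multimapFraction` the per-gene multimapped
#' fraction; `offsetRows` the long-format rows of an [OffsetTable-class];
#' `sfPmf` the event probabilities of an [SFDistribution-class];
#' `asiteValues`/`asiteMethod` the per-gene codon vectors and method name
#' of an [AsiteProfileSet-class].
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("geneIds", "GeneModelSet", function(x) x@info$gene_id)
#' @rdname accessors
setMethod("geneInfo", "GeneModelSet", function(x) x@info)
#' @rdname accessors
setMethod("cdsSequences", "GeneModelSet", function(x) x@sequences)
#' @rdname accessors
setMethod("geneIds", "RiboProfileSet", function(x) geneIds(x@genes))
#' @rdname accessors
setMethod("geneInfo", "RiboProfileSet", function(x) x@genes@info)
#' @rdname accessors
setMethod("profileCounts", "RiboProfileSet",
          function(x) data.table::copy(x@counts))
#' @rdname accessors
setMethod("anchorType", "RiboProfileSet", function(x) x@anchor)
#' @rdname accessors
setMethod("multimapFraction", "RiboProfileSet", function(x) x@multimapFraction)
#' @rdname accessors
setMethod("offsetRows", "OffsetTable", function(x) x@rows)
#' @rdname accessors
setMethod("sfPmf", "SFDistribution", function(x) x@pmf)
#' @rdname accessors
setMethod("asiteValues", "AsiteProfileSet", function(x) x@values)
#' @rdname accessors
setMethod("asiteMethod", "AsiteProfileSet", function(x) x@method)

#' Gene models attached to a profile or A-site set
#'
#' @param x a [RiboProfileSet-class] or [AsiteProfileSet-class].
#' @return The [GeneModelSet-class] the object refers to.
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname geneModels
setMethod("geneModels", "RiboProfileSet", function(x) x@genes)
#' @rdname geneModels
setMethod("geneModels", "AsiteProfileSet", function(x) x@genes)

#' Extract one (gene, size, frame) track
#'
#' Returns the sparse counts of the anchor-nucleotide positions for one
#' fragment size and frame on one gene.
#'
#' @param x a [RiboProfileSet-class].
#' @param gene gene identifier.
#' @param size fragment size in nt.
#' @param frame frame (0, 1 or 2) of the anchor nucleotide.
#' @return list with integer `pos` and numeric `count` (possibly empty).
#' @export
trackCounts <- function(x, gene, size, frame) {
  stopifnot(is(x, "RiboProfileSet"))
  idx <- data.table::data.table(gene_id = as.character(gene),
                                size = as.integer(size),
                                frame = as.integer(frame))
  dt <- x@counts[idx, on = c("gene_id", "size", "frame"), nomatch = NULL]
  list(pos = dt$pos, count = dt$count)
}
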