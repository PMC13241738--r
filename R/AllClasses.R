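#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' DirectedGeneSet: a gene set with optional activation-direction annotations
#'
#' A named collection of protein/gene identifiers. Members may carry an
#' expected direction under pathway activation (+1 = goes up when the pathway
#' is active, -1 = goes down), the convention used by direction-aware pathway
#' activation scoring. A subset of members may be flagged as key regulators,
#' the proteins whose individual differential evidence is required before a
#' signaling module is selected.
#'
#' @slot name single set identifier, unique within a collection.
#' @slot members character vector of unique member identifiers.
#' @slot directions named integer vector (+1/-1); names are a subset of
#'   \code{members}. May be empty for undirected sets.
#' @slot keyRegulators character vector, subset of \code{members}.
#'
#' @examples
#' gs <- DirectedGeneSet("DA degradation signaling",
#'                       members = c("Maoa", "Maob", "Comt"),
#'                       directions = c(Maoa = 1L, Maob = 1L, Comt = 1L),
#'                       keyRegulators = c("Maoa", "Maob", "Comt"))
#' memberIds(gs)
#' @export
setClass("DirectedGeneSet",
         representation(name = "character",
                        members = "character",
                        directions = "integer",
                        keyRegulators = "character"))

setValidity("DirectedGeneSet", function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (length(object@directions)) {
        if (is.null(names(object@directions)) ||
            !all(names(object@directions) %in% object@members))
            msg <- c(msg, "direction annotations must be named by members")
        if (!all(object@directions %in% c(-1L, 1L)))
            msg <- c(msg, "directions must be +1 or -1")
    }
    if (!all(object@keyRegulators %in% object@members))
        msg <- c(msg, "keyRegulators must be a subset of members")
    if (length(msg)) msg else TRUE
})

#' Construct a DirectedGeneSet
#'
#' @param name set identifier.
#' @param members character vector of member identifiers.
#' @param directions optional named vector of +1/-1 expected directions under
#'   activation; names must be members.
#' @param keyRegulators optional character vector of key-regulator members.
#' @return A \linkS4class{DirectedGeneSet}.
#' @export
DirectedGeneSet <- function(name, members, directions = integer(0),
                            keyRegulators = character(0)) {
    if (length(directions) && is.null(names(directions)))
        stop("'directions' must be a named vector")
    new("DirectedGeneSet", name = as.character(name),
        members = as.character(members),
        directions = structure(as.integer(directions),
                               names = names(directions)),
        keyRegulators = as.character(keyRegulators))
}

#' @rdname DirectedGeneSet-accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname DirectedGeneSet-accessors
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))
#' @rdname DirectedGeneSet-accessors
#' @export
setGeneric("memberDirections", function(x) standardGeneric("memberDirections"))
#' @rdname DirectedGeneSet-accessors
#' @export
setGeneric("keyRegulators", function(x) standardGeneric("keyRegulators"))

#' Accessors for DirectedGeneSet
#'
#' @param x a \linkS4class{DirectedGeneSet}.
#' @return \code{setName}: the set identifier; \code{memberIds}: character
#'   vector of members; \code{memberDirections}: named +1/-1 vector (possibly
#'   empty); \code{keyRegulators}: character vector.
#' @name DirectedGeneSet-accessors
#' @aliases setName memberIds memberDirections keyRegulators
NULL

#' @rdname DirectedGeneSet-accessors
setMethod("setName", "DirectedGeneSet", function(x) x@name)
#' @rdname DirectedGeneSet-accessors
setMethod("memberIds", "DirectedGeneSet", function(x) x@members)
#' @rdname DirectedGeneSet-accessors
setMethod("memberDirections", "DirectedGeneSet", function(x) x@directions)
#' @rdname DirectedGeneSet-accessors
setMethod("keyRegulators", "DirectedGeneSet", function(x) x@keyRegulators)

setMethod("show", "DirectedGeneSet", function(object) {
    cat("DirectedGeneSet \"", object@name, "\"\n", sep = "")
    cat("  ", length(object@members), " members",
        if (length(object@directions))
            paste0(" (", length(object@directions), " direction-annotated)"),
        "\n", sep = "")
    if (length(object@keyRegulators))
        cat("  key regulators: ",
            paste(object@keyRegulators, collapse = ", "), "\n", sep = "")
})

#' DirectedGeneSetCollection: an ordered collection of DirectedGeneSet
#'
#' Set names must be unique; the collection behaves like a named list
#' (\code{length}, \code{names}, \code{[[}, \code{[}).
#'
#' @slot sets list of \linkS4class{DirectedGeneSet}.
#' @export
setClass("DirectedGeneSetCollection", representation(sets = "list"))

setValidity("DirectedGeneSetCollection", function(object) {
    if (!all(vapply(object@sets, is, logical(1), "DirectedGeneSet")))
        return("all elements must be DirectedGeneSet objects")
    nm <- vapply(object@sets, setName, character(1))
    if (anyDuplicated(nm))
        return(paste0("duplicate set names: ",
                      paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    TRUE
})

#' Construct a DirectedGeneSetCollection
#'
#' @param ... \linkS4class{DirectedGeneSet} objects, or a single list of them.
#' @return A \linkS4class{DirectedGeneSetCollection}.
#' @export
DirectedGeneSetCollection <- function(...) {
    sets <- list(...)
    if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "DirectedGeneSet"))
        sets <- sets[[1]]
    obj <- new("DirectedGeneSetCollection", sets = unname(sets))
    obj
}

#' @describeIn DirectedGeneSetCollection number of sets
#' @param x,i,object standard list-access arguments.
#' @export
setMethod("length", "DirectedGeneSetCollection", function(x) length(x@sets))

#' @describeIn DirectedGeneSetCollection set names
#' @export
setMethod("names", "DirectedGeneSetCollection",
          function(x) vapply(x@sets, setName, character(1)))

#' @describeIn DirectedGeneSetCollection extract one set by index or name
#' @export
setMethod("[[", "DirectedGeneSetCollection", function(x, i) {
    if (is.character(i)) {
        idx <- match(i, names(x))
        if (is.na(idx)) stop("no set named '", i, "'")
        i <- idx
    }
    x@sets[[i]]
})

#' @describeIn DirectedGeneSetCollection subset the collection
#' @export
setMethod("[", "DirectedGeneSetCollection", function(x, i) {
    if (is.character(i)) i <- match(i, names(x))
    new("DirectedGeneSetCollection", sets = x@sets[i])
})

#' Coerce a collection to a plain list of DirectedGeneSet
#' @param x a DirectedGeneSetCollection.
#' @param ... unused.
#' @export
setMethod("as.list", "DirectedGeneSetCollection", function(x, ...) {
    structure(x@sets, names = names(x))
})

setMethod("show", "DirectedGeneSetCollection", function(object) {
    cat("DirectedGeneSetCollection with", length(object), "sets\n")
    nm <- names(object)
    sz <- vapply(object@sets, function(s) length(memberIds(s)), integer(1))
    dd <- vapply(object@sets, function(s) length(memberDirections(s)) > 0,
                 logical(1))
    for (i in seq_len(min(length(object), 8L)))
        cat(sprintf("  %-32s %3d members%s\n", nm[i], sz[i],
                    if (dd[i]) " [directed]" else ""))
    if (length(object) > 8L) cat("  ...\n")
})
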