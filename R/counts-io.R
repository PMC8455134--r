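# FamilyCountTable construction, accessors, and file readers/writers for
# count tables, annotation maps, gene sets and branch sets.

#' Construct a FamilyCountTable
#'
#' @param counts numeric matrix of non-negative integer gene counts with
#'   family IDs as rownames and species labels as colnames.
#' @return a [FamilyCountTable-class].
#' @examples
#' m <- matrix(c(1L, 0L, 2L, 3L), 2, byrow = TRUE,
#'             dimnames = list(c("OG1", "OG2"), c("sp1", "sp2")))
#' familyCountTable(m)
#' @export
familyCountTable <- function(counts) {
    storage.mode(counts) <- "integer"
    methods::new("FamilyCountTable", counts = counts)
}

#' @describeIn familyCountTable the raw count matrix.
#' @param x a [FamilyCountTable-class].
#' @export
famCounts <- function(x) x@counts

#' @describeIn familyCountTable family (orthogroup) IDs.
#' @export
familyIds <- function(x) rownames(x@counts)

#' @describeIn familyCountTable species labels.
#' @export
speciesLabels <- function(x) colnames(x@counts)

#' Presence/absence matrix of a count table
#'
#' @param x a [FamilyCountTable-class], or a count matrix.
#' @return logical matrix (families x species); presence is count > 0.
#' @export
presenceMatrix <- function(x) {
    m <- if (is(x, "FamilyCountTable")) x@counts else x
    m > 0
}

setMethod("show", "FamilyCountTable", function(object) {
    cat(sprintf("FamilyCountTable: %d families x %d species\n",
                nrow(object@counts), ncol(object@counts)))
    empty <- sum(rowSums(object@counts) == 0)
    if (empty) cat(sprintf("  %d all-zero (empty) families\n", empty))
})

setMethod("[", "FamilyCountTable", function(x, i, j, ..., drop = FALSE) {
    familyCountTable(x@counts[i, j, drop = FALSE])
})

#' Read an orthogroup gene-count table
#'
#' Reads a tab-separated family-by-species count table.  The
#' \code{"orthofinder"} dialect is the \code{Orthogroups.GeneCount.tsv}
#' layout: first column \code{Orthogroup}, one column per species, and an
#' optional trailing \code{Total} column which is validated against the row
#' sums and then dropped.  The \code{"plain"} dialect treats the first
#' column as family IDs whatever its name.
#'
#' All-zero families are retained at load (filtering is a separate step,
#' see [filterForBD()]); their IDs are attached as attribute
#' \code{"emptyFamilies"}.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect \code{"orthofinder"} (default) or \code{"plain"}.
#' @param aliases optional named character vector renaming species columns
#'   (\code{c(old = "new")}); the only renaming mechanism, matching is
#'   otherwise exact.
#' @return a [FamilyCountTable-class].
#' @export
readGeneCounts <- function(path, dialect = c("orthofinder", "plain"),
                           aliases = NULL) {
    dialect <- match.arg(dialect)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("count table needs an ID column and >= 1 species")
    if (dialect == "orthofinder" && colnames(df)[1] != "Orthogroup")
        stop("orthofinder dialect requires first column 'Orthogroup'")
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    total <- NULL
    if (dialect == "orthofinder" && colnames(df)[ncol(df)] == "Total") {
        total <- df[[ncol(df)]]
        df <- df[, -ncol(df), drop = FALSE]
    }
    m <- as.matrix(df)
    if (!is.numeric(m) || any(is.na(m)) || any(m != round(m)))
        stop("non-integer cell in count table")
    if (!is.null(total)) {
        bad <- which(rowSums(m) != total)
        if (length(bad))
            stop("'Total' column disagrees with row sums for: ",
                 paste(utils::head(ids[bad], 5), collapse = ", "))
    }
    if (!is.null(aliases)) {
        hit <- match(colnames(m), names(aliases))
        colnames(m)[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
    }
    rownames(m) <- ids
    out <- familyCountTable(m)
    attr(out, "emptyFamilies") <- ids[rowSums(m) == 0]
    out
}

#' Check that a count table and a tree describe the same species
#'
#' @param counts a [FamilyCountTable-class].
#' @param tree a [TimeTree-class].
#' @return invisibly TRUE; stops with the offending labels otherwise.
#' @export
checkSpeciesMatch <- function(counts, tree) {
    sp <- speciesLabels(counts)
    tl <- tipLabels(tree)
    extra <- setdiff(sp, tl)
    miss <- setdiff(tl, sp)
    if (length(extra) || length(miss))
        stop("species labels disagree with tree tips; ",
             if (length(extra)) paste("not in tree:",
                 paste(extra, collapse = ", ")) else "",
             if (length(miss)) paste(" missing from table:",
                 paste(miss, collapse = ", ")) else "")
    invisible(TRUE)
}

#' Read a protein annotation / family-membership map
#'
#' Expects a TSV with a header and columns \code{protein_id},
#' \code{species}, \code{family_id}, \code{term}; a protein may appear on
#' several rows (one per term) but must always carry the same family.  An
#' empty \code{term} records membership only.
#'
#' @param path path to the TSV file.
#' @return an [AnnotationMap-class].
#' @export
readAnnotationMap <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("protein_id", "species", "family_id", "term")
    if (!all(need %in% colnames(df)))
        stop("annotation map needs columns: ", paste(need, collapse = ", "))
    members <- unique(df[, c("protein_id", "species", "family_id")])
    colnames(members) <- c("protein", "species", "family")
    terms <- df[!is.na(df$term) & nzchar(df$term), c("protein_id", "term")]
    colnames(terms) <- c("protein", "term")
    methods::new("AnnotationMap", members = members, terms = unique(terms))
}

#' Construct an AnnotationMap in code
#'
#' @param members data.frame with columns protein, species, family.
#' @param terms data.frame with columns protein, term (may be empty).
#' @return an [AnnotationMap-class].
#' @export
annotationMap <- function(members,
                          terms = data.frame(protein = character(0),
                                             term = character(0))) {
    methods::new("AnnotationMap", members = members, terms = terms)
}

setMethod("show", "AnnotationMap", function(object) {
    cat(sprintf("AnnotationMap: %d proteins, %d families, %d term links\n",
                nrow(object@members), length(unique(object@members$family)),
                nrow(object@terms)))
})

#' Construct a GeneSet
#'
#' @param families character family IDs (duplicates collapsed).
#' @param name set name.
#' @return a [GeneSet-class].
#' @export
geneSet <- function(families, name = "geneset") {
    methods::new("GeneSet", name = name,
                 families = unique(as.character(families)))
}

#' @describeIn geneSet the family IDs in the set.
#' @param x a [GeneSet-class].
#' @export
setFamilies <- function(x) x@families

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s': %d families\n", object@name,
                length(object@families)))
})

#' Read a gene set and translate it to family IDs
#'
#' Reads a plain-text file with one gene/protein ID per line (lines
#' starting with \code{#} are comments) and maps the IDs to families via
#' the annotation map.  Unmapped IDs are counted and reported with a
#' warning; an empty set after mapping is an error.
#'
#' @param path path to the ID list.
#' @param idMap an [AnnotationMap-class] used for ID-to-family translation.
#' @param name set name (defaults to the file name).
#' @return a [GeneSet-class]; the number of unmapped IDs is attached as
#'   attribute \code{"nUnmapped"}.
#' @export
readGeneSet <- function(path, idMap, name = basename(path)) {
    lines <- readLines(path)
    ids <- trimws(lines[!grepl("^\\s*#", lines)])
    ids <- ids[nzchar(ids)]
    if (!length(ids)) stop("gene set file is empty after comment filtering")
    fam <- idMap@members$family[match(ids, idMap@members$protein)]
    nUnmapped <- sum(is.na(fam))
    fam <- unique(fam[!is.na(fam)])
    if (!length(fam))
        stop("no gene set member could be mapped to a family")
    if (nUnmapped)
        warning(nUnmapped, " gene set member(s) had no family mapping")
    out <- geneSet(fam, name)
    attr(out, "nUnmapped") <- nUnmapped
    out
}

#' Construct a BranchSet
#'
#' @param tree a [TimeTree-class].
#' @param branches integer child-node IDs or character node labels.
#' @param name set name.
#' @return a [BranchSet-class].
#' @export
branchSet <- function(tree, branches, name = "branchset") {
    ids <- if (is.character(branches)) nodeId(tree, branches)
           else as.integer(branches)
    if (any(ids < 1 | ids > nNodes(tree)))
        stop("branch ID outside the tree")
    if (any(ids == rootNode(tree)))
        stop("the root has no branch")
    methods::new("BranchSet", name = name, branches = unique(ids))
}

#' @describeIn branchSet the branch (child node) IDs in the set.
#' @param x a [BranchSet-class].
#' @export
setBranches <- function(x) x@branches

setMethod("show", "BranchSet", function(object) {
    cat(sprintf("BranchSet '%s': %d branches\n", object@name,
                length(object@branches)))
})

#' Read a branch set file
#'
#' One node label per line (species names for tip branches, internal labels
#' such as \code{"N9"} otherwise); \code{#} lines are comments.
#'
#' @param path path to the file.
#' @param tree a [TimeTree-class] naming the branches.
#' @param name set name (defaults to the file name).
#' @return a [BranchSet-class].
#' @export
readBranchSet <- function(path, tree, name = basename(path)) {
    lines <- readLines(path)
    labs <- trimws(lines[!grepl("^\\s*#", lines)])
    labs <- labs[nzchar(labs)]
    if (!length(labs)) stop("branch set file is empty")
    branchSet(tree, labs, name)
}

.configHash <- function(config) {
    # small stable string hash (djb2) of the deparsed configuration
    s <- paste(deparse(config), collapse = "")
    h <- 5381
    for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2^31
    sprintf("%08x", h)
}

#' Write a result table as TSV with a provenance comment
#'
#' All result tables are written with a leading \code{#} comment recording
#' the package version and a hash of the run configuration.
#'
#' @param df a data.frame.
#' @param path output path.
#' @param config optional configuration object to hash into the header.
#' @return the path, invisibly.
#' @export
writeResultTsv <- function(df, path, config = NULL) {
    ver <- as.character(utils::packageVersion("GeneFamEvo"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# GeneFamEvo %s config=%s", ver,
                       .configHash(config)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
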