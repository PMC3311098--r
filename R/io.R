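## File readers and writers. All tabular inputs auto-detect the delimiter
## among tab / comma / whitespace; output is always tab-separated.

.readDelimLines <- function(path, comment = "#") {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    idx <- seq_along(lines)
    keep <- !startsWith(trimws(lines), comment) & nzchar(trimws(lines))
    lines <- lines[keep]
    idx <- idx[keep]
    if (!length(lines)) return(list(fields = list(), lineno = integer()))
    delim <- if (any(grepl("\t", lines[[1]]))) "\t"
             else if (grepl(",", lines[[1]], fixed = TRUE)) ","
             else "[[:space:]]+"
    fields <- strsplit(trimws(lines), delim)
    list(fields = fields, lineno = idx)
}

#' Read one network from an edge-list file
#'
#' One interaction per line, two delimited protein-id columns (tab, comma or
#' whitespace; auto-detected). Lines starting with `#` are ignored.
#' Self-loops are dropped (with a message reporting the count) and duplicate
#' undirected edges are collapsed. Isolated proteins can be supplied through
#' `vertexFile`, one id per line.
#'
#' @param path path to the edge-list file.
#' @param networkId identifier for this network.
#' @param vertexFile optional path to a one-column file of protein ids,
#'   allowing vertices with no interactions.
#' @return a list with components `networkId`, `vertices` (character) and
#'   `edges` (two-column character matrix), suitable for
#'   [NetworkCollection()].
#' @examples
#' f <- tempfile()
#' writeLines(c("A1\tA2", "A2\tA3"), f)
#' net <- readNetworkEdgelist(f, "A")
#' length(net$vertices)
#' @export
readNetworkEdgelist <- function(path, networkId, vertexFile = NULL) {
    parsed <- .readDelimLines(path)
    if (!length(parsed$fields))
        stop("empty edge-list file: ", path)
    bad <- which(vapply(parsed$fields, length, 1L) < 2L)
    if (length(bad))
        stop("malformed line ", parsed$lineno[bad[1]], " in ", path,
             ": expected >= 2 columns")
    from <- vapply(parsed$fields, `[`, "", 1L)
    to <- vapply(parsed$fields, `[`, "", 2L)
    nself <- sum(from == to)
    if (nself)
        message("readNetworkEdgelist: dropped ", nself, " self-loop(s) in ",
                networkId)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    a <- pmin(from, to); b <- pmax(from, to)
    dup <- duplicated(paste(a, b, sep = "\r"))
    verts <- character()
    if (!is.null(vertexFile)) {
        vp <- .readDelimLines(vertexFile)
        verts <- vapply(vp$fields, `[`, "", 1L)
    }
    list(networkId = networkId,
         vertices = sort(unique(c(verts, a, b))),
         edges = cbind(a[!dup], b[!dup]))
}

#' Read a cross-network similarity table
#'
#' Three delimited columns: idA, idB, score (non-negative). Within-network
#' pairs and zero scores are dropped (counts reported via messages); for
#' duplicated unordered pairs the maximum score is kept. Ids are matched
#' against the collection's raw ids first and global ids second, so tables
#' written against the original identifiers keep working after namespacing.
#'
#' @param path path to the table.
#' @param nets a [NetworkCollection-class].
#' @param strict if `TRUE`, an id not present in `nets` is an error;
#'   otherwise such rows are dropped with a warning.
#' @return a [SimilarityMatrix-class] over the collection's protein universe.
#' @examples
#' nc <- NetworkCollection(list(A = rbind(c("A1", "A2")),
#'                              B = rbind(c("B1", "B2"))))
#' f <- tempfile()
#' writeLines("A1\tB1\t20", f)
#' sm <- readSimilarityTable(f, nc)
#' simScore(sm, "A1", "B1")
#' @export
readSimilarityTable <- function(path, nets, strict = FALSE) {
    parsed <- .readDelimLines(path)
    if (!length(parsed$fields))
        stop("empty similarity file: ", path)
    bad <- which(vapply(parsed$fields, length, 1L) < 3L)
    if (length(bad))
        stop("malformed line ", parsed$lineno[bad[1]], " in ", path,
             ": expected 3 columns")
    pa <- vapply(parsed$fields, `[`, "", 1L)
    pb <- vapply(parsed$fields, `[`, "", 2L)
    sc <- suppressWarnings(as.numeric(vapply(parsed$fields, `[`, "", 3L)))
    if (anyNA(sc))
        stop("malformed line ", parsed$lineno[which(is.na(sc))[1]], " in ",
             path, ": score not numeric")
    if (any(sc < 0))
        stop("negative similarity score at line ",
             parsed$lineno[which(sc < 0)[1]], " in ", path)
    glob <- proteins(nets)
    raw <- rawIds(nets)
    resolve <- function(ids) {
        out <- rep(NA_character_, length(ids))
        hit <- ids %in% glob
        out[hit] <- ids[hit]
        if (any(!hit)) {
            rawUnique <- raw[!duplicated(raw) & !(raw %in% raw[duplicated(raw)])]
            m <- match(ids[!hit], rawUnique)
            out[!hit] <- names(rawUnique)[m]
        }
        out
    }
    ga <- resolve(pa); gb <- resolve(pb)
    unknown <- is.na(ga) | is.na(gb)
    if (any(unknown)) {
        if (strict)
            stop("unknown protein at line ",
                 parsed$lineno[which(unknown)[1]], " in ", path)
        warning("readSimilarityTable: dropped ", sum(unknown),
                " row(s) referencing unknown proteins")
    }
    ga <- ga[!unknown]; gb <- gb[!unknown]; sc <- sc[!unknown]
    nn <- proteinNetwork(nets)
    nWithin <- sum(nn[ga] == nn[gb])
    nZero <- sum(sc == 0)
    if (nWithin) message("readSimilarityTable: dropped ", nWithin,
                         " within-network pair(s)")
    if (nZero) message("readSimilarityTable: dropped ", nZero,
                       " zero-score row(s)")
    SimilarityMatrix(ga, gb, sc, nets = nets)
}

#' Write / read an alignment file
#'
#' One match-set per line, tab-separated protein ids (the layout used by
#' IsoRankN output). `writeAlignment` writes raw ids when a collection is
#' given and its raw ids are unambiguous, global ids otherwise. A sidecar
#' file `<path>.unaligned` listing covered-by-no-match-set proteins is
#' written when `nets` is supplied and `unalignedSidecar` is `TRUE`.
#'
#' @param alignment an [Alignment-class].
#' @param path output (or input) file path.
#' @param nets optional [NetworkCollection-class] used for raw-id output, the
#'   unaligned sidecar, and id resolution on read.
#' @param unalignedSidecar write the `<path>.unaligned` sidecar?
#' @return `writeAlignment` returns `path` invisibly; `readAlignment`
#'   returns an [Alignment-class].
#' @examples
#' aln <- Alignment(list(c("A1", "B1"), c("A2", "B2")))
#' f <- tempfile()
#' writeAlignment(aln, f)
#' identical(matchSets(readAlignment(f)), matchSets(aln))
#' @export
writeAlignment <- function(alignment, path, nets = NULL,
                           unalignedSidecar = !is.null(nets)) {
    ms <- matchSets(alignment)
    translate <- identity
    if (!is.null(nets)) {
        raw <- rawIds(nets)
        if (!anyDuplicated(raw))
            translate <- function(p) unname(raw[p])
    }
    lines <- vapply(ms, function(s) paste(translate(s), collapse = "\t"), "")
    writeLines(lines, path)
    if (isTRUE(unalignedSidecar) && !is.null(nets)) {
        un <- setdiff(proteins(nets), alignedProteins(alignment))
        writeLines(translate(sort(un)), paste0(path, ".unaligned"))
    }
    invisible(path)
}

#' @rdname writeAlignment
#' @export
readAlignment <- function(path, nets = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- strsplit(lines, "\t", fixed = TRUE)
    if (!is.null(nets)) {
        raw <- rawIds(nets)
        if (!anyDuplicated(raw)) {
            back <- stats::setNames(names(raw), raw)
            sets <- lapply(sets, function(s) {
                hit <- s %in% names(back)
                s[hit] <- back[s[hit]]
                s
            })
        }
    }
    if (anyDuplicated(unlist(sets)))
        stop("alignment file violates disjointness: a protein appears twice")
    Alignment(sets)
}

#' Read a protein annotation table
#'
#' Plain format: two delimited columns, protein id and term id, one
#' annotation per line. GAF format (`format = "gaf"`): lines starting with
#' `!` are skipped and columns 2 (DB object id) and 5 (term id) of the
#' tab-separated file are used.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"gaf"`.
#' @return an [AnnotationMap-class].
#' @export
readAnnotationTable <- function(path, format = c("tsv", "gaf")) {
    format <- match.arg(format)
    if (format == "gaf") {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
        fields <- strsplit(lines, "\t", fixed = TRUE)
        bad <- which(vapply(fields, length, 1L) < 5L)
        if (length(bad)) stop("malformed GAF line ", bad[1], " in ", path)
        prot <- vapply(fields, `[`, "", 2L)
        term <- vapply(fields, `[`, "", 5L)
    } else {
        parsed <- .readDelimLines(path)
        if (!length(parsed$fields)) return(AnnotationMap())
        bad <- which(vapply(parsed$fields, length, 1L) < 2L)
        if (length(bad))
            stop("malformed line ", parsed$lineno[bad[1]], " in ", path)
        prot <- vapply(parsed$fields, `[`, "", 1L)
        term <- vapply(parsed$fields, `[`, "", 2L)
    }
    AnnotationMap(data.frame(protein = prot, term = term,
                             stringsAsFactors = FALSE))
}

#' Read a per-protein domain p-value table
#'
#' Three delimited columns: protein id, domain id, p-value in (0, 1].
#'
#' @param path path to the table.
#' @return a named list: protein id -> named numeric vector of domain
#'   p-values, usable with [domainSimilarity()].
#' @export
readDomainPValues <- function(path) {
    parsed <- .readDelimLines(path)
    if (!length(parsed$fields))
        stop("empty domain p-value file: ", path)
    bad <- which(vapply(parsed$fields, length, 1L) < 3L)
    if (length(bad))
        stop("malformed line ", parsed$lineno[bad[1]], " in ", path)
    prot <- vapply(parsed$fields, `[`, "", 1L)
    dom <- vapply(parsed$fields, `[`, "", 2L)
    pv <- suppressWarnings(as.numeric(vapply(parsed$fields, `[`, "", 3L)))
    if (anyNA(pv) || any(pv <= 0) || any(pv > 1))
        stop("domain p-values must be numbers in (0, 1]")
    out <- lapply(split(seq_along(prot), prot),
                  function(i) stats::setNames(pv[i], dom[i]))
    out
}
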