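#' @include AllClasses.R
NULL

# Fixed-column PDB reader/writer. The parser is deliberately strict about
# the coordinate/serial fields (a malformed record is an error naming the
# line) and deliberately lenient about everything PDB files are routinely
# sloppy about (short lines, missing element columns).

.parseAtomLine <- function(line, lineno) {
  line <- sprintf("%-80s", line)
  num <- function(s, what, required = TRUE) {
    s <- trimws(s)
    if (!nzchar(s)) {
      if (required)
        stop(sprintf("malformed PDB record at line %d: empty %s field",
                     lineno, what), call. = FALSE)
      return(NA_real_)
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v))
      stop(sprintf("malformed PDB record at line %d: bad %s field '%s'",
                   lineno, what, s), call. = FALSE)
    v
  }
  name <- trimws(substr(line, 13, 16))
  element <- trimws(substr(line, 77, 78))
  if (!nzchar(element)) {
    stripped <- gsub("[^A-Za-z]", "", name)
    element <- toupper(substr(stripped, 1, 1))
  } else {
    element <- toupper(element)
  }
  occ <- num(substr(line, 55, 60), "occupancy", required = FALSE)
  bf <- num(substr(line, 61, 66), "bfactor", required = FALSE)
  list(serial = as.integer(num(substr(line, 7, 11), "serial")),
       name = name,
       element = element,
       altloc = trimws(substr(line, 17, 17)),
       resname = trimws(substr(line, 18, 20)),
       chain = trimws(substr(line, 22, 22)),
       resseq = as.integer(num(substr(line, 23, 26), "resseq")),
       icode = trimws(substr(line, 27, 27)),
       x = num(substr(line, 31, 38), "x"),
       y = num(substr(line, 39, 46), "y"),
       z = num(substr(line, 47, 54), "z"),
       occupancy = if (is.na(occ)) 1 else occ,
       bfactor = if (is.na(bf)) 0 else bf,
       is_hetero = startsWith(line, "HETATM"))
}

.collapseAltlocs <- function(at, policy) {
  if (!any(nzchar(at$altloc))) return(at)
  key <- paste(at$chain, at$resseq, at$icode, at$name, sep = "\r")
  keep <- logical(nrow(at))
  for (idx in split(seq_len(nrow(at)), key)) {
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    pick <- if (policy == "first") {
      idx[1L]
    } else {
      # highest occupancy, ties broken by altloc letter order
      ord <- order(-at$occupancy[idx], at$altloc[idx])
      idx[ord[1L]]
    }
    keep[pick] <- TRUE
  }
  at <- at[keep, , drop = FALSE]
  at$altloc <- ""
  at
}

.newStructure <- function(at, modelId, title) {
  rownames(at) <- NULL
  new("PDBStructure", modelId = as.integer(modelId), atoms = at,
      title = title)
}

#' Parse PDB-format text into structures
#'
#' Reads ATOM/HETATM/MODEL/ENDMDL/TITLE records of a fixed-column PDB file.
#' Each MODEL becomes one [PDBStructure-class]; a file without MODEL records
#' yields a single structure. Alternate locations are collapsed to one atom
#' per (chain, residue, name) according to `altloc`. Record order is
#' preserved. HETATM waters and ligands are retained; downstream operations
#' filter by residue name.
#'
#' @param text either a single string of PDB text (may contain newlines),
#'   a character vector of lines, or the path of an existing file.
#' @param altloc `"highest_occupancy"` (default; ties broken by altloc
#'   letter) or `"first"`.
#' @return list of [PDBStructure-class], one per model.
#' @examples
#' s <- makeTwoChainScaffold(nRes = 3)
#' parsePDB(writePDB(s))[[1]]
#' @export
parsePDB <- function(text, altloc = c("highest_occupancy", "first")) {
  altloc <- match.arg(altloc)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    startsWith(lines, "ATOM") & nchar(trimws(rec)) == 4 |
    startsWith(lines, "HETATM")
  if (!any(is_atom))
    stop("empty input: no ATOM or HETATM records found", call. = FALSE)

  title <- trimws(paste(substring(lines[startsWith(lines, "TITLE")], 11),
                        collapse = " "))
  models <- list()
  cur <- list()
  cur_model <- NA_integer_
  n_model_rec <- 0L
  flush <- function() {
    if (!length(cur)) return()
    at <- do.call(rbind, lapply(cur, function(a) as.data.frame(a)))
    at <- .collapseAltlocs(at, altloc)
    mid <- if (is.na(cur_model)) length(models) + 1L else cur_model
    models[[length(models) + 1L]] <<- .newStructure(at, mid, title)
    cur <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "MODEL")) {
      flush()
      n_model_rec <- n_model_rec + 1L
      m <- suppressWarnings(as.integer(trimws(substr(ln, 7, 14))))
      cur_model <- if (is.na(m)) n_model_rec else m
    } else if (startsWith(ln, "ENDMDL")) {
      flush()
      cur_model <- NA_integer_
    } else if (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")) {
      cur[[length(cur) + 1L]] <- .parseAtomLine(ln, i)
    }
  }
  flush()
  models
}

.formatAtomName <- function(name, element) {
  if (nchar(name) >= 4L) return(substr(name, 1, 4))
  if (nchar(element) == 2L) return(sprintf("%-4s", name))
  sprintf(" %-3s", name)
}

#' Write structures as PDB-format text
#'
#' Inverse of [parsePDB()]: fixed-column records, coordinates to 3
#' decimals, MODEL/ENDMDL framing when more than one structure is given
#' (the multi-model file is the package's trajectory container), TER after
#' each polymer chain.
#'
#' @param structures a [PDBStructure-class] or list of them.
#' @param path optional file to write to.
#' @return the PDB text, invisibly when `path` is given.
#' @export
writePDB <- function(structures, path = NULL) {
  if (is(structures, "PDBStructure")) structures <- list(structures)
  stopifnot(all(vapply(structures, is, logical(1), "PDBStructure")))
  multi <- length(structures) > 1L
  out <- character(0)
  title <- if (length(structures) && nzchar(structures[[1L]]@title))
    sprintf("TITLE     %s", structures[[1L]]@title) else character(0)
  out <- c(out, title)
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    validObject(s)
    at <- s@atoms
    if (nrow(at) && any(nchar(at$chain) > 1L))
      stop("chain id longer than one character cannot be written in PDB format",
           call. = FALSE)
    if (multi) out <- c(out, sprintf("MODEL     %4d", s@modelId))
    if (nrow(at)) {
      recs <- vapply(seq_len(nrow(at)), function(i) {
        a <- at[i, ]
        sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                if (a$is_hetero) "HETATM" else "ATOM",
                a$serial %% 100000L,
                .formatAtomName(a$name, a$element), a$altloc, a$resname,
                a$chain, a$resseq, a$icode, a$x, a$y, a$z,
                a$occupancy, a$bfactor, a$element)
      }, character(1))
      # TER after each contiguous run of polymer atoms of one chain,
      # preserving record order
      runs <- rle(paste(at$chain, at$is_hetero))
      ends <- cumsum(runs$lengths)
      starts <- c(1L, head(ends, -1L) + 1L)
      lines_k <- character(0)
      for (r in seq_along(ends)) {
        lines_k <- c(lines_k, recs[starts[r]:ends[r]])
        if (!at$is_hetero[ends[r]]) lines_k <- c(lines_k, "TER")
      }
      out <- c(out, lines_k)
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
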