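#' Read a receptor structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a flat atom table with one
#' row per resolved atom.  Alternate locations are resolved per
#' `altloc_policy`; waters (residue name HOH) and hetero records are
#' flagged.  Insertion codes are kept as part of the residue key.
#'
#' @param path PDB file path.
#' @param altloc_policy `"highest_occupancy"` (default; ties go to the
#'   altloc encountered first) or `"first"` (keep the first altloc seen for
#'   each atom).
#' @param source_id provenance label stored on the structure; defaults to
#'   the file name.
#' @return an object of class `agstruct`: list with `atoms` (data.frame
#'   with columns record, serial, name, res_name, chain, res_seq, insert,
#'   x, y, z, occupancy, element, is_water, is_hetero) and `source_id`.
#' @export
read_pdb <- function(path, altloc_policy = c("highest_occupancy", "first"),
                     source_id = basename(path)) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  .ag_validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE,
                         hex = FALSE, multi = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("empty structure: no ATOM/HETATM records in ", path,
                          call. = FALSE)
  receptor_structure(data.frame(
    record = at$type, serial = at$eleno, name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    res_name = at$resid, chain = ifelse(is.na(at$chain), "", at$chain),
    res_seq = at$resno, insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = .ag_pdb_element(at$elesy, at$elety),
    stringsAsFactors = FALSE
  ), source_id = source_id, altloc_policy = altloc_policy)
}

# Minimal well-formedness check so coordinate corruption is reported with a
# line number rather than silently coerced to NA downstream.
.ag_validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (k in which(rec)) {
    ln <- lines[k]
    if (nchar(ln) < 54)
      stop(sprintf("PDB parse error at line %d: truncated coordinate record", k),
           call. = FALSE)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("PDB parse error at line %d: malformed coordinate field", k),
           call. = FALSE)
  }
  invisible(TRUE)
}

# Element from the PDB element column when present, else inferred from the
# atom-name columns per PDB v3 conventions (column 13 non-blank => two-letter
# element or H of long hydrogen names).
.ag_pdb_element <- function(elesy, elety) {
  el <- ifelse(is.na(elesy) | elesy == "", NA_character_,
               paste0(toupper(substr(elesy, 1, 1)),
                      tolower(substr(elesy, 2, 2))))
  miss <- is.na(el)
  if (any(miss)) {
    guess <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", elety[miss])))
    two <- substr(guess, 1, 2)
    one <- substr(guess, 1, 1)
    two_ok <- paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))) %in%
      .ag_supported_elements & nchar(two) == 2
    el[miss] <- ifelse(two_ok & !(one %in% c("C", "N", "O", "S", "P", "H")),
                       paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
                       one)
  }
  bad <- which(!(el %in% .ag_supported_elements))
  if (length(bad))
    stop(sprintf("unknown element for atom '%s' (record %d)",
                 elety[bad[1]], bad[1]), call. = FALSE)
  el
}

#' Construct a receptor structure from an atom table
#'
#' @param atoms data.frame as documented in [read_pdb()]; `altloc`,
#'   `occupancy`, `serial` and `record` are optional.
#' @param source_id provenance label.
#' @param altloc_policy how to resolve alternate locations (see
#'   [read_pdb()]).
#' @return an `agstruct`.
#' @export
receptor_structure <- function(atoms, source_id = "in-memory",
                               altloc_policy = "highest_occupancy") {
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$record))
    atoms$record <- ifelse(atoms$res_name %in% .ag_standard_residues,
                           "ATOM", "HETATM")
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms <- .ag_resolve_altlocs(atoms, altloc_policy)
  atoms$is_water <- atoms$res_name == "HOH"
  atoms$is_hetero <- atoms$record == "HETATM"
  atoms$res_key <- paste(atoms$chain, atoms$res_seq, atoms$insert, sep = "|")
  .ag_check_elements(atoms$element, source_id)
  dup <- duplicated(atoms[, c("res_key", "name")])
  if (any(dup))
    stop(sprintf("duplicate atom name '%s' in residue %s after altloc resolution",
                 atoms$name[dup][1], atoms$res_key[dup][1]), call. = FALSE)
  structure(list(atoms = atoms, source_id = source_id), class = "agstruct")
}

.ag_resolve_altlocs <- function(atoms, policy) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$res_seq, atoms$insert, atoms$name, sep = "|")
  keep <- logical(nrow(atoms))
  for (k in split(seq_len(nrow(atoms)), key)) {
    if (length(k) == 1L || all(atoms$altloc[k] == "")) { keep[k] <- TRUE; next }
    pick <- if (policy == "first") k[1]
            else k[which.max(atoms$occupancy[k])]  # which.max: tie -> first
    keep[pick] <- TRUE
  }
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.agstruct <- function(x, ...) {
  r <- residues(x)
  cat(sprintf("<structure '%s': %d atoms, %d residues (%d water, %d hetero)>\n",
              x$source_id, nrow(x$atoms), nrow(r), sum(r$is_water),
              sum(r$is_hetero & !r$is_water)))
  invisible(x)
}

#' Residue table of a structure
#'
#' One row per residue in file order, with chain, author numbering
#' (insertion code kept in the key), 3-letter name and flags.
#'
#' @param struct an `agstruct`.
#' @return data.frame with columns res_key, chain, res_seq, insert,
#'   res_name, is_water, is_hetero, n_atoms.
#' @export
residues <- function(struct) {
  at <- struct$atoms
  first <- !duplicated(at$res_key)
  data.frame(res_key = at$res_key[first], chain = at$chain[first],
             res_seq = at$res_seq[first], insert = at$insert[first],
             res_name = at$res_name[first], is_water = at$is_water[first],
             is_hetero = at$is_hetero[first],
             n_atoms = as.vector(table(factor(at$res_key,
                                              levels = at$res_key[first]))),
             stringsAsFactors = FALSE)
}

#' Select a residue's atoms
#' @param struct an `agstruct`.
#' @param res_name 3-letter residue name to select (e.g. a ligand code).
#' @param chain optional chain restriction.
#' @param res_seq optional residue number restriction.
#' @return data.frame subset of `struct$atoms`.
#' @export
select_residue <- function(struct, res_name, chain = NULL, res_seq = NULL) {
  at <- struct$atoms
  sel <- at$res_name == res_name
  if (!is.null(chain)) sel <- sel & at$chain == chain
  if (!is.null(res_seq)) sel <- sel & at$res_seq == res_seq
  if (!any(sel)) stop("residue not found: ", res_name, call. = FALSE)
  at[sel, , drop = FALSE]
}

#' Write a receptor structure to a PDB file
#'
#' Coordinates are written at 3 decimals (standard PDB fixed format) via
#' bio3d.
#'
#' @param struct an `agstruct`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(struct, path) {
  at <- struct$atoms
  bio3d::write.pdb(file = path, type = at$record, eleno = at$serial,
                   elety = at$name, resid = at$res_name, chain = at$chain,
                   resno = at$res_seq, insert = ifelse(at$insert == "", NA,
                                                       at$insert),
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   o = at$occupancy, b = rep(0, nrow(at)),
                   elesy = toupper(at$element))
  invisible(path)
}

#' Coordinates of a structure (or atom-table subset)
#' @param x an `agstruct` or an atom data.frame.
#' @return n x 3 matrix, Angstrom.
#' @export
struct_coords <- function(x) {
  at <- if (inherits(x, "agstruct")) x$atoms else x
  as.matrix(at[, c("x", "y", "z")])
}

#' Read docked ligand poses from an SDF (V2000) file
#'
#' Parses a multi-molecule MDL SD file.  Coordinates, elements, bonds,
#' `M  CHG` formal charges, titles and data tags are preserved;
#' [write_sdf()] round-trips coordinates bit-identically at 4 decimals.
#' V3000 connection tables are rejected.
#'
#' @param path SDF path.
#' @param score_tag data-tag name holding an external docking score
#'   (default `"CHEMPLP"`); when the tag is absent the pose's score is
#'   `NA`.
#' @return list of `agpose` objects.
#' @export
read_sdf <- function(path, score_tag = "CHEMPLP") {
  lines <- readLines(path, warn = FALSE)
  poses <- list()
  pos <- 1L
  idx <- 0L
  while (pos <= length(lines)) {
    # skip stray blank lines between records
    while (pos <= length(lines) && !nzchar(trimws(lines[pos])) ) pos <- pos + 1L
    if (pos > length(lines)) break
    idx <- idx + 1L
    end <- pos
    while (end <= length(lines) && trimws(lines[end]) != "$$$$") end <- end + 1L
    block <- lines[pos:(min(end, length(lines)))]
    block <- block[trimws(block) != "$$$$"]
    poses[[idx]] <- .ag_parse_sdf_block(block, idx, score_tag)
    pos <- end + 1L
  }
  poses
}

.ag_parse_sdf_block <- function(block, mol_index, score_tag) {
  if (length(block) < 4)
    stop(sprintf("SDF molecule %d: truncated header", mol_index), call. = FALSE)
  counts <- block[4]
  if (grepl("V3000", counts))
    stop(sprintf("SDF molecule %d: V3000 connection tables are not supported; supply V2000",
                 mol_index), call. = FALSE)
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop(sprintf("SDF molecule %d: malformed counts line", mol_index),
         call. = FALSE)
  need <- 4 + natoms + nbonds
  if (length(block) < need)
    stop(sprintf("SDF molecule %d: counts line promises %d atoms / %d bonds but block is short",
                 mol_index, natoms, nbonds), call. = FALSE)
  alines <- block[4 + seq_len(natoms)]
  atoms <- data.frame(
    x = as.numeric(substr(alines, 1, 10)),
    y = as.numeric(substr(alines, 11, 20)),
    z = as.numeric(substr(alines, 21, 30)),
    element = trimws(substr(alines, 32, 34)),
    charge = 0L, stringsAsFactors = FALSE)
  if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z)))
    stop(sprintf("SDF molecule %d: malformed atom coordinates", mol_index),
         call. = FALSE)
  atoms$name <- paste0(atoms$element, seq_len(natoms))
  bonds <- if (nbonds) {
    blines <- block[4 + natoms + seq_len(nbonds)]
    data.frame(i = as.integer(substr(blines, 1, 3)),
               j = as.integer(substr(blines, 4, 6)),
               order = as.numeric(substr(blines, 7, 9)))
  } else NULL
  # properties block: M  CHG lines
  rest <- block[-seq_len(4 + natoms + nbonds)]
  for (ln in grep("^M  CHG", rest, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    nset <- f[1]
    for (k in seq_len(nset)) atoms$charge[f[2 * k]] <- f[2 * k + 1]
  }
  # data tags
  tagpos <- grep("^> *<", rest)
  props <- character()
  for (tp in tagpos) {
    tag <- sub("^> *<([^>]*)>.*$", "\\1", rest[tp])
    val <- if (tp + 1 <= length(rest)) trimws(rest[tp + 1]) else ""
    props[tag] <- val
  }
  mol <- molecule(atoms, bonds, title = block[1], properties = props)
  score <- if (score_tag %in% names(props))
    suppressWarnings(as.numeric(props[[score_tag]])) else NA_real_
  ligand_pose(mol, score)
}

#' Write ligand poses to an SDF (V2000) file
#'
#' Coordinates are written at 4 decimals; formal charges as `M  CHG`
#' lines; properties as data tags.  Deterministic: the same input always
#' produces byte-identical output.
#'
#' @param poses list of `agpose` (or `agmol`) objects.
#' @param path output path.
#' @param score_tag tag used to store a non-`NA` docking score.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(poses, path, score_tag = "CHEMPLP") {
  con <- file(path, "wb")  # binary: fixed \n endings for byte-identity
  on.exit(close(con))
  for (p in poses) {
    mol <- if (inherits(p, "agpose")) p$molecule else p
    props <- mol$properties
    if (inherits(p, "agpose") && !is.na(p$docking_score))
      props[score_tag] <- format(p$docking_score)
    writeLines(c(mol$title, "  agscreen", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(mol$atoms), nrow(mol$bonds)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       mol$atoms$x, mol$atoms$y, mol$atoms$z,
                       mol$atoms$element), con)
    if (nrow(mol$bonds))
      writeLines(sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                         as.integer(mol$bonds$order)), con)
    chg <- which(mol$atoms$charge != 0L)
    for (k in chg)
      writeLines(sprintf("M  CHG  1 %3d %3d", k, mol$atoms$charge[k]), con)
    writeLines("M  END", con)
    for (tag in names(props))
      writeLines(c(sprintf("> <%s>", tag), props[[tag]], ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Write a results table to TSV/CSV
#'
#' Deterministic rendering: fixed column order as given, numbers at 6
#' significant digits, no quoting surprises, LF line endings.
#'
#' @param rows data.frame.
#' @param path output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  out <- rows
  for (cl in names(out))
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
      out[[cl]] <- signif(out[[cl]], 6)
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
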