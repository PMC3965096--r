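# residue-name vocabularies used when deciding what counts as a polymer
# amino acid. Non-standard amino acids carrying a CA/CB are admitted.
.standard_aa <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS",
                  "ILE","LEU","LYS","MET","PHE","PRO","SER","THR","TRP",
                  "TYR","VAL")
.nonstandard_aa <- c("MSE","SEC","PYL","SEP","TPO","PTR","CSO","HYP","MLY",
                     "KCX","CME","CSD","FME","OCS")
.water_names <- c("HOH","WAT","DOD","H2O")
.nucleic_names <- c("A","C","G","U","I","DA","DC","DG","DT","DU","DI")

#' Select the representative atom of one residue
#'
#' The contact metric reduces each residue to a single point: the C-beta
#' atom, or C-alpha for glycine (which has no side chain). Residues other
#' than glycine that lack a C-beta fall back to C-alpha; residues with
#' neither atom yield nothing (counted, not fatal). When alternate
#' locations are present the highest-occupancy one wins, ties broken by
#' altloc label sort order.
#'
#' @param residue_record data.frame of the atom rows of ONE residue, with
#'   columns `elety` (atom name), `alt` (altloc or NA), `o` (occupancy),
#'   `resid` (3-letter residue name), `resno` (author residue number),
#'   `x`, `y`, `z`.
#' @return A list with `coord` (length-3 numeric), `atom_used` (`"CB"` or
#'   `"CA"`), `residue_name`, `seq_index` — or `NULL` if the residue has
#'   neither a C-beta nor a C-alpha.
#' @export
select_representative_atom <- function(residue_record) {
  rr <- residue_record
  want <- if (identical(rr$resid[1], "GLY")) "CA" else "CB"
  rows <- rr[rr$elety == want, , drop = FALSE]
  used <- want
  if (nrow(rows) == 0L && want == "CB") {
    rows <- rr[rr$elety == "CA", , drop = FALSE]
    used <- "CA"
  }
  if (nrow(rows) == 0L) return(NULL)
  if (nrow(rows) > 1L) {
    occ <- ifelse(is.na(rows$o), 1, rows$o)
    alt <- ifelse(is.na(rows$alt), "", rows$alt)
    rows <- rows[order(-occ, alt, method = "radix"), , drop = FALSE]
  }
  list(coord = c(rows$x[1], rows$y[1], rows$z[1]),
       atom_used = used,
       residue_name = rr$resid[1],
       seq_index = rr$resno[1])
}

# split one chain's residue-level table into assembly copies: a new copy
# starts wherever the author residue numbering restarts (decreases).
.assign_copies <- function(resno) {
  if (length(resno) == 0L) return(integer())
  cumsum(c(TRUE, diff(resno) < 0))
}

# build the chains of one BioUnit from a bio3d-style atom data.frame
.build_chains <- function(atom) {
  is_polymer <- (!(atom$resid %in% c(.water_names, .nucleic_names))) &
    (atom$type == "ATOM" | atom$resid %in% .nonstandard_aa)
  atom <- atom[is_polymer, , drop = FALSE]
  if (nrow(atom) == 0L) return(list())
  atom$chain[is.na(atom$chain)] <- " "
  # residue identity: chain + author number + insertion code, in file order
  ins <- if ("insert" %in% names(atom)) ifelse(is.na(atom$insert), "", atom$insert) else ""
  rid <- paste(atom$chain, atom$resno, ins, sep = "|")
  rid_f <- factor(rid, levels = unique(rid))
  chains <- list()
  for (ch in unique(atom$chain)) {
    sel <- atom$chain == ch
    res_ids <- unique(rid_f[sel])
    pts <- vector("list", length(res_ids))
    res_tab <- split(atom[sel, , drop = FALSE], droplevels(rid_f[sel]))
    res_tab <- res_tab[as.character(res_ids)]   # keep file order
    n_skipped <- 0L
    for (i in seq_along(res_tab)) {
      rp <- select_representative_atom(res_tab[[i]])
      if (is.null(rp)) n_skipped <- n_skipped + 1L else pts[[i]] <- rp
    }
    pts <- pts[!vapply(pts, is.null, logical(1))]
    if (length(pts) == 0L) next
    pdf <- data.frame(
      seq_index = vapply(pts, `[[`, 0, "seq_index"),
      residue_name = vapply(pts, `[[`, "", "residue_name"),
      x = vapply(pts, function(p) p$coord[1], 0),
      y = vapply(pts, function(p) p$coord[2], 0),
      z = vapply(pts, function(p) p$coord[3], 0),
      atom_used = vapply(pts, `[[`, "", "atom_used"),
      stringsAsFactors = FALSE)
    copies <- .assign_copies(pdf$seq_index)
    for (cp in unique(copies)) {
      csel <- copies == cp
      chains[[length(chains) + 1L]] <- list(
        chain_id = ch, copy_index = as.integer(cp),
        points = pdf[csel, , drop = FALSE],
        n_skipped = if (cp == 1L) n_skipped else 0L)
    }
  }
  chains
}

.new_biounit <- function(structure_id, assembly_id, chains) {
  structure(list(structure_id = structure_id, assembly_id = assembly_id,
                 chains = chains), class = "biounit")
}

#' @export
print.biounit <- function(x, ...) {
  cat("<biounit> ", x$structure_id, " assembly ", x$assembly_id, ": ",
      length(x$chains), " chain(s) [",
      paste(vapply(x$chains, function(c)
        paste0(c$chain_id, "(", nrow(c$points), ")"), ""), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

# infer structure id / assembly id from a file name like 1abc.pdb1
.ids_from_path <- function(path) {
  base <- basename(path)
  asm <- "1"
  m <- regmatches(base, regexec("\\.pdb([0-9]+)$", base))[[1]]
  if (length(m) == 2L) asm <- m[2]
  sid <- sub("\\.(pdb[0-9]*|ent|cif|mmcif)$", "", base)
  list(structure_id = sid, assembly_id = asm)
}

#' Read biological-unit structures
#'
#' Reads a pre-expanded biological assembly from a PDB or mmCIF file and
#' reduces every polymer amino-acid residue to its representative atom
#' (see [select_representative_atom()]). Waters, ligands and nucleic acids
#' are excluded. For multi-model files only the first model is used. An
#' mmCIF file with several `data_` blocks yields one assembly per block.
#'
#' @param path structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension, falling
#'   back to content sniffing).
#' @return A list of `biounit` objects (usually length 1).
#' @export
read_biounit <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif"
    else if (grepl("\\.(pdb[0-9]*|ent)$", path, ignore.case = TRUE)) "pdb"
    else {
      head1 <- readLines(path, n = 1L)
      if (grepl("^data_", head1)) "mmcif" else "pdb"
    }
  }
  ids <- .ids_from_path(path)
  units <- list()
  if (format == "pdb") {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE)),
      error = function(e) stop("cannot parse PDB file ", path, ": ",
                               conditionMessage(e)))
    chains <- .build_chains(pdb$atom)
    if (length(chains))
      units[[1]] <- .new_biounit(ids$structure_id, ids$assembly_id, chains)
  } else {
    blocks <- .split_cif_blocks(path)
    for (bi in seq_along(blocks)) {
      tf <- tempfile(fileext = ".cif")
      on.exit(unlink(tf), add = TRUE)
      writeLines(blocks[[bi]]$lines, tf)
      cif <- tryCatch(
        suppressWarnings(bio3d::read.cif(tf, verbose = FALSE)),
        error = function(e) stop("cannot parse mmCIF block '",
                                 blocks[[bi]]$name, "' in ", path, ": ",
                                 conditionMessage(e)))
      chains <- .build_chains(cif$atom)
      if (length(chains))
        units[[length(units) + 1L]] <-
          .new_biounit(ids$structure_id,
                       if (length(blocks) > 1L) as.character(bi) else ids$assembly_id,
                       chains)
    }
  }
  if (length(units) == 0L)
    stop("empty structure: no polymer amino-acid chains in ", path)
  units
}

# split an mmCIF file into its data_ blocks (most files have exactly one)
.split_cif_blocks <- function(path) {
  lines <- readLines(path)
  starts <- grep("^data_", lines)
  if (length(starts) == 0L) stop("not an mmCIF file (no data_ block): ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i)
    list(name = sub("^data_", "", lines[starts[i]]),
         lines = lines[starts[i]:ends[i]]))
}
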