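# Conformational-ensemble input/output and residue-level atom selection.
#
# The interchange format is multi-model PDB (MODEL/ENDMDL).  Residues are keyed
# by (chain id, author residue number, insertion code) throughout; author
# numbering is never altered.

#' Construct a molecular structure
#'
#' A lightweight container for one conformation: an atom table plus an
#' n-by-3 coordinate matrix (Angstrom).
#'
#' @param atoms data frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `icode`, `element`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  req <- c("serial", "name", "resname", "chain", "resno", "icode", "element")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) != nrow(xyz))
    stop("coordinate count (", nrow(xyz), ") does not match atom count (", nrow(atoms), ")")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  rownames(atoms) <- NULL
  obj <- list(atoms = atoms, xyz = xyz)
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("structure3d: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), nrow(rt), length(unique(rt$chain))))
  invisible(x)
}

# Residue table in order of first appearance: chain, resno, icode, resname,
# key, and the residue's ordinal position within its chain (used for
# sequence-neighbor logic).
residue_table <- function(x) {
  atoms <- if (inherits(x, "structure3d")) x$atoms
  else if (inherits(x, "conf_ensemble")) x$topology$atoms
  else stop("expected a structure3d or conf_ensemble")
  first <- !duplicated(atoms$key)
  rt <- atoms[first, c("chain", "resno", "icode", "resname", "key")]
  rownames(rt) <- NULL
  rt$chain_pos <- stats::ave(seq_len(nrow(rt)), rt$chain, FUN = seq_along)
  dup <- duplicated(rt$key)
  if (any(dup))
    stop("residue identifiers not unique within chain: ",
         paste(unique(rt$key[dup]), collapse = ", "))
  rt
}

#' Construct a conformational ensemble
#'
#' @param topology a [structure3d()] giving the atom/residue topology shared by
#'   every frame.
#' @param frames list of n-by-3 coordinate matrices, or an `n x 3 x F` array,
#'   all congruent with `topology`.
#' @param frame_interval time between frames, or `"unitless"`.
#' @return an object of class `conf_ensemble`.
#' @export
conf_ensemble <- function(topology, frames, frame_interval = "unitless") {
  stopifnot(inherits(topology, "structure3d"))
  n <- nrow(topology$xyz)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    coords <- frames
  } else {
    if (!is.list(frames) || length(frames) < 1L) stop("ensemble needs >= 1 frame")
    coords <- array(NA_real_, c(n, 3L, length(frames)))
    for (f in seq_along(frames)) {
      fr <- as.matrix(frames[[f]])
      if (!all(dim(fr) == c(n, 3L)))
        stop("frame ", f, " is not congruent with the topology (", n, " atoms)")
      coords[, , f] <- fr
    }
  }
  if (dim(coords)[1] != n) stop("frames do not match topology atom count")
  if (dim(coords)[3] < 1L) stop("ensemble needs >= 1 frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  obj <- list(topology = topology, coords = coords, frame_interval = frame_interval)
  class(obj) <- "conf_ensemble"
  obj
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("conf_ensemble: %d frames, %d atoms, %d residues (interval: %s)\n",
              n_frames(x), dim(x$coords)[1], nrow(residue_table(x)),
              as.character(x$frame_interval)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `conf_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Coerce a structure to a single-frame ensemble
#' @param x a `structure3d` or `conf_ensemble`.
#' @param frame_interval see [conf_ensemble()].
#' @return a `conf_ensemble`.
#' @export
as_ensemble <- function(x, frame_interval = "unitless") {
  if (inherits(x, "conf_ensemble")) return(x)
  conf_ensemble(x, list(x$xyz), frame_interval)
}

# Extract frame f as a structure3d.
ensemble_frame <- function(ensemble, f) {
  structure3d(ensemble$topology$atoms, ensemble$coords[, , f, drop = TRUE])
}

.water_resnames <- c("HOH", "WAT", "DOD", "TIP", "TIP3", "SOL")

parse_pdb_atom_line <- function(line, lineno) {
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop(sprintf("unreadable %s in PDB record at line %d: '%s'",
                               what, lineno, line))
    v
  }
  list(
    record  = trimws(substr(line, 1, 6)),
    serial  = num(substr(line, 7, 11), "serial"),
    name    = trimws(substr(line, 13, 16)),
    altloc  = substr(line, 17, 17),
    resname = trimws(substr(line, 18, 20)),
    chain   = substr(line, 22, 22),
    resno   = num(substr(line, 23, 26), "residue number"),
    icode   = substr(line, 27, 27),
    x = num(substr(line, 31, 38), "x coordinate"),
    y = num(substr(line, 39, 46), "y coordinate"),
    z = num(substr(line, 47, 54), "z coordinate"),
    element = trimws(substr(line, 77, 78))
  )
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single-frame ensemble.  The topology is taken from the
#' first model and every subsequent model must contain the same atoms in the
#' same order (a mismatch is a hard error naming the offending model).
#'
#' Hydrogens (and deuteriums), waters, and heteroatom records are dropped on
#' read by default, so the ensemble is an amino-acid heavy-atom model.
#' Alternate locations other than blank/`A` are discarded.
#'
#' @param path path to a PDB file.
#' @param keep_hetero keep `HETATM` records (waters are always dropped)?
#' @param frame_interval recorded on the returned ensemble; metadata only.
#' @return a [conf_ensemble()].
#' @export
read_multimodel_pdb <- function(path, keep_hetero = FALSE,
                                frame_interval = "unitless") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- startsWith(rec, "ATOM") | startsWith(rec, "HETATM")
  is_model <- startsWith(rec, "MODEL")
  model_of <- cumsum(is_model)
  if (!any(is_model)) model_of <- rep(1L, length(lines))
  model_of[model_of == 0L] <- 1L

  keep_line <- function(a) {
    el <- if (nzchar(a$element)) toupper(a$element)
          else toupper(substr(gsub("^[0-9]*", "", a$name), 1, 1))
    if (el %in% c("H", "D")) return(FALSE)
    if (toupper(a$resname) %in% .water_resnames) return(FALSE)
    if (a$record == "HETATM" && !keep_hetero) return(FALSE)
    if (!(a$altloc %in% c(" ", "", "A"))) return(FALSE)
    TRUE
  }

  models <- sort(unique(model_of[is_atom]))
  if (!length(models)) stop("no coordinate records in ", path)

  frames <- list()
  topo_atoms <- NULL
  topo_sig <- NULL
  for (mi in seq_along(models)) {
    idx <- which(is_atom & model_of == models[mi])
    parsed <- lapply(idx, function(i) parse_pdb_atom_line(lines[i], i))
    parsed <- parsed[vapply(parsed, keep_line, logical(1))]
    if (!length(parsed)) stop("model ", mi, " contains no retained atoms")
    at <- data.frame(
      serial  = as.integer(vapply(parsed, `[[`, numeric(1), "serial")),
      name    = vapply(parsed, `[[`, character(1), "name"),
      resname = vapply(parsed, `[[`, character(1), "resname"),
      chain   = vapply(parsed, `[[`, character(1), "chain"),
      resno   = as.integer(vapply(parsed, `[[`, numeric(1), "resno")),
      icode   = vapply(parsed, function(a) sub(" ", "", a$icode), character(1)),
      element = vapply(parsed, function(a) {
        if (nzchar(a$element)) toupper(a$element)
        else toupper(substr(gsub("^[0-9]*", "", a$name), 1, 1))
      }, character(1)),
      stringsAsFactors = FALSE
    )
    xyz <- cbind(vapply(parsed, `[[`, numeric(1), "x"),
                 vapply(parsed, `[[`, numeric(1), "y"),
                 vapply(parsed, `[[`, numeric(1), "z"))
    sig <- paste(at$name, at$resname, at$chain, at$resno, at$icode, sep = "|")
    if (is.null(topo_atoms)) {
      topo_atoms <- at
      topo_sig <- sig
    } else {
      if (nrow(at) != nrow(topo_atoms))
        stop(sprintf("model %d has %d atoms but model 1 has %d atoms",
                     mi, nrow(at), nrow(topo_atoms)))
      if (!identical(sig, topo_sig))
        stop(sprintf("model %d atom ordering/identity differs from model 1", mi))
    }
    frames[[mi]] <- xyz
  }
  conf_ensemble(structure3d(topo_atoms, frames[[1]]), frames, frame_interval)
}

format_pdb_atom_name <- function(name) {
  # element-aligned atom-name field (cols 13-16)
  if (nchar(name) >= 4) substr(name, 1, 4)
  else formatC(paste0(" ", name), width = -4)
}

#' Write a structure or ensemble as a (multi-model) PDB file
#'
#' @param x a `structure3d` or `conf_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  ens <- as_ensemble(x)
  at <- ens$topology$atoms
  nm <- vapply(at$name, format_pdb_atom_name, character(1))
  nf <- n_frames(ens)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$coords[, , f, drop = TRUE]
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      as.integer(at$serial) %% 100000L, nm, at$resname, at$chain,
      as.integer(at$resno) %% 10000L,
      ifelse(nzchar(at$icode), at$icode, " "),
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00, at$element), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Select residue-representative atoms
#'
#' Maps every residue to the atom indices that represent it under one of three
#' modes: `"calpha"` (alpha carbons), `"allatom"` (every retained atom), or
#' `"sidechain"` (side-chain heavy atoms, i.e. everything except backbone
#' N/CA/C/O/OXT).  Glycine has no side-chain heavy atom and falls back to its
#' alpha carbon in `"sidechain"` mode so that every residue remains a network
#' node; any other residue left without atoms is an error.
#'
#' @param x a `structure3d` or `conf_ensemble`.
#' @param mode `"calpha"`, `"allatom"` or `"sidechain"` (aliases
#'   `"alpha-carbon"`, `"all-atom"`, `"side-chain-heavy"` are accepted).
#' @return an object of class `residue_selection`: the residue table plus a
#'   list of atom-index vectors, one per residue.
#' @export
select_residue_atoms <- function(x, mode = c("calpha", "allatom", "sidechain")) {
  aliases <- c("alpha-carbon" = "calpha", "all-atom" = "allatom",
               "side-chain-heavy" = "sidechain")
  if (is.character(mode) && length(mode) == 1L && mode %in% names(aliases))
    mode <- aliases[[mode]]
  mode <- match.arg(mode)
  atoms <- if (inherits(x, "structure3d")) x$atoms else x$topology$atoms
  rt <- residue_table(x)
  by_res <- split(seq_len(nrow(atoms)), factor(atoms$key, levels = rt$key))
  sel <- vector("list", nrow(rt))
  for (i in seq_len(nrow(rt))) {
    idx <- by_res[[i]]
    keep <- switch(mode,
      calpha   = idx[atoms$name[idx] == "CA"],
      allatom  = idx,
      sidechain = {
        sc <- idx[!(atoms$name[idx] %in% .backbone_names)]
        if (!length(sc) && toupper(rt$resname[i]) == "GLY")
          sc <- idx[atoms$name[idx] == "CA"]
        sc
      })
    if (!length(keep))
      stop("residue ", rt$key[i], " (", rt$resname[i],
           ") has no atoms under mode '", mode, "'")
    sel[[i]] <- keep
  }
  obj <- list(mode = mode, residues = rt, atom_idx = sel)
  class(obj) <- "residue_selection"
  obj
}

#' @export
print.residue_selection <- function(x, ...) {
  cat(sprintf("residue_selection: mode '%s', %d residues, %d atoms\n",
              x$mode, nrow(x$residues), length(unlist(x$atom_idx))))
  invisible(x)
}

#' Create a per-residue value profile
#'
#' @param residues residue table (`chain`, `resno`, `icode`, `resname`, ...).
#' @param value numeric vector, one value per residue.
#' @param value_name name recorded for the value column.
#' @return a data frame of class `residue_profile`.
#' @export
residue_profile <- function(residues, value, value_name = "value") {
  stopifnot(length(value) == nrow(residues))
  p <- data.frame(chain = residues$chain, resno = residues$resno,
                  icode = residues$icode %||% "", resname = residues$resname,
                  value = as.numeric(value), stringsAsFactors = FALSE)
  p$key <- residue_key(p$chain, p$resno, p$icode)
  attr(p, "value_name") <- value_name
  class(p) <- c("residue_profile", "data.frame")
  p
}

#' Write a residue profile to TSV
#'
#' Columns: chain, resno (author numbering, insertion code appended verbatim),
#' resname, value.  Rows are ordered by chain, residue number, insertion code,
#' so output is deterministic.
#'
#' @param profile a [residue_profile()] (or data frame with the same columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  req <- c("chain", "resno", "resname", "value")
  miss <- setdiff(req, names(profile))
  if (length(miss)) stop("profile lacks columns: ", paste(miss, collapse = ", "))
  icode <- profile$icode %||% rep("", nrow(profile))
  o <- order(profile$chain, profile$resno, icode)
  out <- data.frame(chain = profile$chain[o],
                    resno = paste0(profile$resno[o], icode[o]),
                    resname = profile$resname[o],
                    value = sprintf("%.12e", profile$value[o]),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a residue profile written by [write_profile()]
#' @param path TSV path.
#' @return a [residue_profile()].
#' @export
read_profile <- function(path) {
  d <- utils::read.delim(path, colClasses = c("character", "character",
                                              "character", "numeric"))
  resno <- as.integer(sub("([0-9]+).*", "\\1", d$resno))
  icode <- sub("^[0-9]+", "", d$resno)
  residue_profile(data.frame(chain = d$chain, resno = resno, icode = icode,
                             resname = d$resname, stringsAsFactors = FALSE),
                  d$value)
}
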