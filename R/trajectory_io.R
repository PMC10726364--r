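## Trajectory ensemble container and multi-model PDB / XYZ I/O.
##
## An ensemble holds M molecules x F frames of coordinates plus one resolved
## ring-pair selection per molecule and an amide-state label. Coordinates are
## Angstrom throughout (PDB convention); indices are 1-based.

CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))

#' Amide-state label
#'
#' The fixed cis/trans configuration assigned to each backbone amide bond of
#' a sequence, in short form: one character per bond, 'c' (cis) or 't'
#' (trans), e.g. "cc", "ct", "tc", "tt" for a two-bond sequence.
#'
#' @param x a character scalar of 'c'/'t' characters.
#' @return an `amide_state_label` object.
#' @export
amide_state_label <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) >= 1L)
  if (!grepl("^[ct]+$", x)) {
    stop("amide-state label must use only 'c' (cis) and 't' (trans): got '", x, "'")
  }
  structure(x, class = "amide_state_label")
}

#' @export
print.amide_state_label <- function(x, ...) {
  cat("<amide state>", unclass(x), "\n")
  invisible(x)
}

#' Ring-pair selection for one molecule
#'
#' Identifies the ipso and para carbons of the two consecutive phenyl rings
#' of a molecule by (1-based) indices into the ensemble's atom table. Ring 1
#' is the ring nearer the N-terminus (lower residue index).
#'
#' @param molecule_id identifier (character or integer).
#' @param ring1_ipso,ring1_para,ring2_ipso,ring2_para atom indices.
#' @param ring1_residue_index,ring2_residue_index sequence positions of the
#'   two ring-bearing residues; ring1 must precede ring2.
#' @return a `ring_pair_selection` object.
#' @export
ring_pair_selection <- function(molecule_id, ring1_ipso, ring1_para,
                                ring2_ipso, ring2_para,
                                ring1_residue_index, ring2_residue_index) {
  idx <- c(ring1_ipso, ring1_para, ring2_ipso, ring2_para)
  stopifnot(length(idx) == 4L, all(idx >= 1L), all(idx == round(idx)))
  if (anyDuplicated(idx)) stop("ring atom indices must be distinct")
  if (!(ring1_residue_index < ring2_residue_index)) {
    stop("ring1 must be nearer the N-terminus (ring1_residue_index < ring2_residue_index)")
  }
  structure(list(molecule_id = molecule_id,
                 ring1_ipso = as.integer(ring1_ipso),
                 ring1_para = as.integer(ring1_para),
                 ring2_ipso = as.integer(ring2_ipso),
                 ring2_para = as.integer(ring2_para),
                 ring1_residue_index = as.integer(ring1_residue_index),
                 ring2_residue_index = as.integer(ring2_residue_index)),
            class = "ring_pair_selection")
}

#' Built-in ring-atom selection template
#'
#' Maps ring-bearing residue names to the atom names of the ipso and para
#' carbons. The ipso carbon is the ring carbon bonded to the side-chain
#' methylene (CG in standard phenylalanine nomenclature) and the para carbon
#' sits three ring bonds away (CZ). Built-in entries cover the benzyl
#' peptoid residue (NF) and phenylalanine (PHE, PHD); add or override
#' entries for other naming schemes.
#'
#' @param ... additional entries, e.g. `BNZ = c(ipso = "C1", para = "C4")`.
#' @return a named list of `c(ipso = , para = )` character pairs.
#' @export
ring_template <- function(...) {
  tpl <- list(NF  = c(ipso = "CG", para = "CZ"),
              PHE = c(ipso = "CG", para = "CZ"),
              PHD = c(ipso = "CG", para = "CZ"))
  extra <- list(...)
  for (nm in names(extra)) {
    e <- extra[[nm]]
    stopifnot(all(c("ipso", "para") %in% names(e)))
    tpl[[nm]] <- e[c("ipso", "para")]
  }
  tpl
}

#' Trajectory ensemble container
#'
#' Assembles coordinates, an atom table and per-molecule ring selections
#' into the labelled multi-molecule structure the descriptor functions
#' consume.
#'
#' @param coords numeric array of dim (n_frames, n_atoms, 3), Angstrom.
#' @param atoms data.frame with one row per atom: columns `elety` (atom
#'   name), `resid` (residue name), `resno` (residue number), `mol`
#'   (molecule index, 1-based, order-stable across frames).
#' @param label an [amide_state_label()] (or string coerced to one), or NULL.
#' @param selection a template from [ring_template()] used to resolve the
#'   two phenyl rings of each molecule, or a pre-built list of
#'   [ring_pair_selection()] objects (one per molecule).
#' @param frame_interval time per frame; metadata only, never used in
#'   statistics.
#' @param validate check ring geometry (ipso-para distance) in every frame
#'   and warn about broken molecules (distance > 3 Angstrom).
#' @return a `trajectory_ensemble` object with fields `coords`, `atoms`,
#'   `selections`, `label`, `n_frames`, `n_molecules`, `frame_interval`.
#' @export
trajectory_ensemble <- function(coords, atoms, label = NULL,
                                selection = ring_template(),
                                frame_interval = NULL, validate = TRUE) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  stopifnot(is.data.frame(atoms),
            all(c("elety", "resid", "resno", "mol") %in% names(atoms)))
  if (dim(coords)[2] != nrow(atoms)) {
    stop("format error: coordinate array has ", dim(coords)[2],
         " atoms but atom table has ", nrow(atoms))
  }
  if (dim(coords)[1] < 1L) stop("ensemble must contain at least one frame")
  if (!is.null(label) && !inherits(label, "amide_state_label")) {
    label <- amide_state_label(label)
  }
  mols <- unique(atoms$mol)
  selections <- if (is.list(selection) && length(selection) &&
                    inherits(selection[[1]], "ring_pair_selection")) {
    if (length(selection) != length(mols)) {
      stop("selection error: need exactly one ring_pair_selection per molecule")
    }
    selection
  } else {
    lapply(mols, function(m) resolve_ring_pair(atoms, m, selection))
  }
  ens <- structure(list(coords = coords,
                        atoms = atoms,
                        selections = selections,
                        label = label,
                        n_frames = dim(coords)[1],
                        n_molecules = length(mols),
                        frame_interval = frame_interval),
                   class = "trajectory_ensemble")
  if (validate) validate_ensemble(ens)
  ens
}

#' Resolve the ring-pair selection of one molecule from a name template
#' @noRd
resolve_ring_pair <- function(atoms, mol, template) {
  rows <- which(atoms$mol == mol)
  sub <- atoms[rows, , drop = FALSE]
  ring_rows <- which(sub$resid %in% names(template))
  if (!length(ring_rows)) {
    stop("selection error: molecule ", mol,
         " has no residues matching the ring template (",
         paste(names(template), collapse = ", "), ")")
  }
  ring_res <- sort(unique(sub$resno[ring_rows]))
  if (length(ring_res) != 2L) {
    stop("selection error: molecule ", mol, " has ", length(ring_res),
         " ring-bearing residues; exactly 2 required")
  }
  pick <- function(resno, role) {
    resname <- sub$resid[sub$resno == resno][1L]
    want <- template[[resname]][[role]]
    hit <- which(sub$resno == resno & sub$elety == want)
    if (length(hit) != 1L) {
      stop("selection error: molecule ", mol, ", residue ", resno,
           ": atom '", want, "' (", role, ") matched ", length(hit), " atoms")
    }
    rows[hit]
  }
  ring_pair_selection(
    molecule_id = mol,
    ring1_ipso = pick(ring_res[1], "ipso"),
    ring1_para = pick(ring_res[1], "para"),
    ring2_ipso = pick(ring_res[2], "ipso"),
    ring2_para = pick(ring_res[2], "para"),
    ring1_residue_index = ring_res[1],
    ring2_residue_index = ring_res[2]
  )
}

#' Flag broken molecules by intra-ring carbon distances
#'
#' Intramolecular descriptors assume molecules are whole (no periodic-image
#' splits). The ipso-para diameter of an intact phenyl ring is ~2.78
#' Angstrom; any value above 3 Angstrom in any frame marks the molecule as
#' broken and triggers a warning.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @return invisibly, the integer indices of broken molecules.
#' @export
validate_ensemble <- function(ensemble) {
  nf <- ensemble$n_frames
  broken <- integer(0)
  for (m in seq_len(ensemble$n_molecules)) {
    sel <- ensemble$selections[[m]]
    for (pair in list(c(sel$ring1_ipso, sel$ring1_para),
                      c(sel$ring2_ipso, sel$ring2_para))) {
      a <- ensemble$coords[, pair[1], , drop = FALSE]; dim(a) <- c(nf, 3)
      b <- ensemble$coords[, pair[2], , drop = FALSE]; dim(b) <- c(nf, 3)
      if (any(rownorm3(a - b) > 3)) { broken <- c(broken, m); break }
    }
  }
  if (length(broken)) {
    warning("broken molecules (intra-ring C-C distance > 3 A): ",
            paste(broken, collapse = ", "),
            "; trajectories must be pre-wrapped molecule-whole")
  }
  invisible(broken)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory ensemble> ", x$n_molecules, " molecules x ", x$n_frames,
      " frames (", dim(x$coords)[2], " atoms/frame)\n", sep = "")
  if (!is.null(x$label)) cat("  amide state:", unclass(x$label), "\n")
  invisible(x)
}

#' Read a trajectory ensemble
#'
#' Reads a multi-model PDB (MODEL/ENDMDL-delimited frames; molecules
#' partitioned by chain identifier) or a multi-frame XYZ file (molecules
#' partitioned by fixed atom-count blocks, since XYZ has no chain concept)
#' and resolves the ring-pair selection of every molecule. Both formats are
#' self-contained, so no separate topology file is needed.
#'
#' @param path input file.
#' @param format "pdb", "xyz", or "auto" (from the file extension).
#' @param selection a [ring_template()] (or list of pre-built selections).
#' @param label optional [amide_state_label()] or short-form string.
#' @param atoms_per_molecule required for XYZ: atoms in each molecule block.
#' @param frame_interval optional time per frame (metadata).
#' @param ... passed to [trajectory_ensemble()].
#' @return a `trajectory_ensemble`.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "xyz"),
                          selection = ring_template(), label = NULL,
                          atoms_per_molecule = NULL, frame_interval = NULL,
                          ...) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", xyz = "xyz",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    mol <- match(at$chain, unique(at$chain))
    atoms <- data.frame(elety = at$elety, resid = at$resid,
                        resno = at$resno, mol = mol,
                        stringsAsFactors = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    na <- nrow(atoms)
    if (ncol(xyz) != 3L * na) {
      stop("format error: coordinate columns (", ncol(xyz),
           ") do not match 3 x atom count (", 3L * na, ")")
    }
    coords <- aperm(array(t(xyz), dim = c(3L, na, nrow(xyz))), c(3L, 2L, 1L))
  } else {
    parsed <- read_xyz_frames(path)
    na <- nrow(parsed$atoms)
    if (is.null(atoms_per_molecule)) {
      atoms_per_molecule <- if (is.na(parsed$mol_atoms)) na else parsed$mol_atoms
    }
    if (na %% atoms_per_molecule != 0L) {
      stop("format error: ", na, " atoms per frame not divisible by ",
           "atoms_per_molecule = ", atoms_per_molecule)
    }
    atoms <- data.frame(
      elety = parsed$atoms$name,
      resid = parsed$atoms$resid,
      resno = parsed$atoms$resno,
      mol = rep(seq_len(na %/% atoms_per_molecule), each = atoms_per_molecule),
      stringsAsFactors = FALSE
    )
    coords <- parsed$coords
  }
  trajectory_ensemble(coords, atoms, label = label, selection = selection,
                      frame_interval = frame_interval, ...)
}

## Extended-XYZ frame blocks: "natoms\ncomment\nNAME x y z ...". Atom names
## are written as RESID:RESNO:NAME when produced by write_ensemble so that
## residue structure survives the round trip; bare element/name tokens are
## also accepted (resid "UNK", resno = atom order).
#' @noRd
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: empty XYZ file")
  i <- 1L; frames <- list(); atoms <- NULL; mol_atoms <- NA_integer_
  while (i <= length(lines)) {
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na < 1L) stop("format error: bad atom count at line ", i)
    if (i + 1L + na > length(lines)) {
      stop("format error: truncated XYZ frame starting at line ", i)
    }
    if (is.na(mol_atoms)) {
      hit <- regmatches(lines[i + 1L],
                        regexec("mol_atoms=([0-9]+)", lines[i + 1L]))[[1]]
      if (length(hit) == 2L) mol_atoms <- as.integer(hit[2])
    }
    block <- lines[(i + 2L):(i + 1L + na)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    name <- vapply(toks, `[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("format error: non-numeric coordinates near line ", i)
    if (is.null(atoms)) {
      tagged <- grepl(":", name, fixed = TRUE)
      resid <- ifelse(tagged, vapply(strsplit(name, ":"), `[`, "", 1L), "UNK")
      resno <- ifelse(tagged,
                      as.integer(vapply(strsplit(name, ":"), `[`, "", 2L)),
                      seq_along(name))
      elety <- ifelse(tagged, vapply(strsplit(name, ":"), `[`, "", 3L), name)
      atoms <- data.frame(name = elety, resid = resid, resno = resno,
                          stringsAsFactors = FALSE)
    } else if (nrow(atoms) != na) {
      stop("format error: frame atom counts differ (", nrow(atoms),
           " vs ", na, ")")
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  coords <- array(0, dim = c(length(frames), nrow(atoms), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  list(atoms = atoms, coords = coords, mol_atoms = mol_atoms)
}

#' Write a trajectory ensemble
#'
#' Writes a multi-model PDB (one MODEL per frame, molecules as chains) or a
#' multi-frame XYZ file re-readable by [read_ensemble()]. PDB coordinates
#' carry three decimals (1e-3 Angstrom precision); XYZ is written with
#' full precision.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param path output file.
#' @param format "pdb" or "xyz".
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, format = c("pdb", "xyz")) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  format <- match.arg(format)
  if (ensemble$n_frames < 1L) stop("cannot write an ensemble with 0 frames")
  na <- nrow(ensemble$atoms)
  if (format == "pdb") {
    nmol <- ensemble$n_molecules
    if (nmol > length(CHAIN_ALPHABET)) {
      stop("PDB output supports at most ", length(CHAIN_ALPHABET),
           " molecules (chain identifiers); write XYZ instead")
    }
    xyz <- matrix(aperm(ensemble$coords, c(3L, 2L, 1L)),
                  nrow = ensemble$n_frames, byrow = TRUE)
    bio3d::write.pdb(file = path, xyz = xyz,
                     elety = ensemble$atoms$elety,
                     resid = ensemble$atoms$resid,
                     resno = ensemble$atoms$resno,
                     chain = CHAIN_ALPHABET[ensemble$atoms$mol],
                     eleno = seq_len(na))
  } else {
    con <- file(path, "w"); on.exit(close(con))
    name <- sprintf("%s:%d:%s", ensemble$atoms$resid, ensemble$atoms$resno,
                    ensemble$atoms$elety)
    for (f in seq_len(ensemble$n_frames)) {
      writeLines(c(as.character(na),
                   sprintf("frame %d mol_atoms=%d", f,
                           na %/% ensemble$n_molecules)), con)
      writeLines(sprintf("%s %.9f %.9f %.9f", name,
                         ensemble$coords[f, , 1],
                         ensemble$coords[f, , 2],
                         ensemble$coords[f, , 3]), con)
    }
  }
  invisible(path)
}
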