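# Readers and writers: PDB, XYZ, COLVAR-style tables, FES grids, PLUMED
# export. PDB coordinates are Angstrom at the file boundary and nm internally
# (exact conversion by 0.1); all writers are deterministic byte-for-byte.

#' Read a PDB structure
#'
#' Parses ATOM/HETATM/MODEL/TER records through the standard bio3d reader
#' after validating the fixed-width coordinate fields; unknown records are
#' ignored (with their count reported as an attribute). Multi-model files
#' yield one coordinate set per model.
#'
#' @param path PDB file path
#' @return object of class \code{structure_record}: \code{atoms} data frame
#'   (serial, name, resname, resid, chain, x, y, z in Angstrom),
#'   \code{models} (list of nm coordinate matrices), \code{source}
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record (truncated coordinates) at line ", i)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("malformed coordinate field at line ", i)
    }
  }
  known <- is_atom | grepl("^(MODEL|ENDMDL|TER|END|REMARK|HEADER|TITLE|CRYST1|CONECT|MASTER|SEQRES)", lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(serial = at$eleno, name = at$elety, resname = at$resid,
                      resid = at$resno, chain = at$chain,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  n_models <- nrow(pdb$xyz)
  models <- lapply(seq_len(n_models), function(m)
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE) * 0.1)
  structure(list(atoms = atoms, models = models,
                 source = sub("\\.pdb$", "", basename(path))),
            class = "structure_record",
            n_ignored = sum(!known & nzchar(lines)))
}

#' Write a minimal PDB file
#' @param atoms data frame with serial, name, resname, resid, chain columns
#' @param coords coordinate matrix in nm (converted to Angstrom on write)
#' @param path output path
#' @export
write_pdb <- function(atoms, coords, path) {
  xyz <- coords * 10
  lines <- sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                   atoms$serial, atoms$name, atoms$resname,
                   ifelse(is.na(atoms$chain) | atoms$chain == "", "A", atoms$chain),
                   atoms$resid, xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory as XYZ
#'
#' One block per frame; the comment line carries the time in ps. Coordinates
#' are written in nm.
#' @param traj a \code{trajectory} (or a frames matrix with a times vector)
#' @param path output path
#' @param times frame times (taken from the trajectory if omitted)
#' @param element element symbol per site
#' @export
write_xyz <- function(traj, path, times = NULL, element = "C") {
  frames <- if (inherits(traj, "trajectory")) traj$frames else traj
  if (is.null(times)) times <- if (inherits(traj, "trajectory")) traj$times
                               else seq_len(nrow(frames)) - 1
  if (is.null(dim(frames))) frames <- matrix(frames, ncol = 1)
  n_sites <- if (length(dim(frames)) == 3) dim(frames)[2] else 1
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(if (length(dim(frames)) == 3) dim(frames)[1] else nrow(frames))) {
    fr <- if (length(dim(frames)) == 3) matrix(frames[i, , ], ncol = 3)
          else matrix(frames[i, ], nrow = 1)
    if (ncol(fr) < 3)  # low-dimensional toy coordinates: pad to xyz
      fr <- cbind(fr, matrix(0, nrow(fr), 3 - ncol(fr)))
    writeLines(c(sprintf("%d", nrow(fr)),
                 sprintf("time= %.6f ps", times[i]),
                 sprintf("%s %.9g %.9g %.9g", element, fr[, 1], fr[, 2], fr[, 3])),
               con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#' @param path XYZ file
#' @return list with \code{frames} (n_frames x n_sites x 3, nm) and
#'   \code{times} (ps)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1
  frames <- list()
  times <- numeric(0)
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- as.integer(trimws(lines[i]))
    tm <- regmatches(lines[i + 1], regexec("time= *([-0-9.eE+]+)", lines[i + 1]))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    block <- lines[(i + 2):(i + 1 + n)]
    coords <- do.call(rbind, lapply(strsplit(trimws(block), "[ \t]+"), function(p)
      as.numeric(p[2:4])))
    frames[[length(frames) + 1]] <- coords
    i <- i + 2 + n
  }
  arr <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
  list(frames = arr, times = times)
}

#' Write a COLVAR-style whitespace table
#'
#' PLUMED dialect: a \code{#! FIELDS time ...} header followed by one row per
#' frame; values are printed with 15 significant digits so that
#' write-read-write round-trips are byte-identical.
#'
#' @param table data frame whose first column is \code{time}
#' @param path output path
#' @export
write_colvar <- function(table, path) {
  if (names(table)[1] != "time") stop("first column must be 'time'")
  if (anyDuplicated(names(table))) stop("duplicate column names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(table), collapse = " ")), con)
  body <- do.call(paste, c(lapply(table, function(col) sprintf("%.15g", col)),
                           sep = " "))
  writeLines(body, con)
  invisible(path)
}

#' Read a COLVAR-style whitespace table
#' @param path COLVAR file with a \code{#! FIELDS ...} header
#' @return data frame
#' @export
read_colvar <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^#!\\s+FIELDS\\s+", header)) stop("missing '#! FIELDS' header")
  fields <- strsplit(sub("^#!\\s+FIELDS\\s+", "", header), "\\s+")[[1]]
  if (anyDuplicated(fields)) stop("duplicate column names in header")
  if (!"time" %in% fields) stop("table has no time column")
  df <- read.table(path, header = FALSE, skip = 1,
                   col.names = fields, check.names = FALSE)
  df
}

#' Write a 1D or 2D free-energy surface as a TSV grid
#' @param fes a \code{fes} or \code{fes2d}
#' @param path output path
#' @export
write_fes_tsv <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kT\t%.10g", fes$kT), con)
  if (inherits(fes, "fes2d")) {
    writeLines(sprintf("# axes\t%s\t%s", fes$axis_names[1], fes$axis_names[2]), con)
    df <- expand.grid(x = fes$centers_x, y = fes$centers_y)
    df$F <- as.vector(fes$F)
    write.table(format(df, digits = 10), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    df <- data.frame(cv = fes$centers, F = fes$F)
    write.table(format(df, digits = 10), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Export a trained HLDA CV as a PLUMED input block
#'
#' Emits one DISTANCE line per contact (atom serial numbers resolved against
#' the structure) and a COMBINE line carrying the coefficients, so the
#' trained CV can drive an external engine. Deterministic ordering; distances
#' are in nm, matching the coefficients' unit convention.
#'
#' @param cv an \code{hlda_cv} with a contact set
#' @param structure a \code{structure_record}
#' @param label PLUMED label of the combined CV
#' @return character vector of PLUMED input lines
#' @export
export_plumed_cv <- function(cv, structure, label = "hlda") {
  if (is.null(cv$contacts) || nrow(cv$contacts) == 0)
    stop("CV has no contact set to export")
  n <- nrow(cv$contacts)
  serial_of <- function(sel) {
    idx <- resolve_selector(sel, structure = structure)
    structure$atoms$serial[idx]
  }
  dlines <- vapply(seq_len(n), function(i)
    sprintf("d%d: DISTANCE ATOMS=%d,%d", i,
            serial_of(cv$contacts$sel_a[i]), serial_of(cv$contacts$sel_b[i])),
    character(1))
  combine <- sprintf("%s: COMBINE ARG=%s COEFFICIENTS=%s PERIODIC=NO", label,
                     paste0("d", seq_len(n), collapse = ","),
                     paste(sprintf("%.10g", cv$coefficients), collapse = ","))
  c("# distances in nm; coefficients apply to nm", dlines, combine)
}

#' Serialize a toy model's defining parameters to a YAML config
#'
#' Stores the constructor arguments (not the derived tilt), so reading the
#' config rebuilds the model through the same root-finding path and
#' reproduces it exactly.
#'
#' @param model a \code{toy_model}
#' @param path output path
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    kind = if (model$dim == 1L) "double_well" else "flip",
    delta_g_target = model$delta_g_target,
    barrier = model$params$a,
    temperature = model$temperature)
  if (model$dim == 2L) {
    cfg <- c(cfg, list(
      coupling = model$coupling,
      ligand_strength = model$ligand_strength,
      ymid = model$params$ymid, yamp = model$params$yamp,
      gk = model$params$gk, masses = model$params$mass,
      sigma_f = model$feature$sigma_f))
  }
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' Rebuild a toy model from a YAML config
#' @param path config path written by \code{\link{write_model_config}}
#' @return a \code{toy_model}
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("kind", "delta_g_target", "barrier", "temperature", "coupling",
             "ligand_strength", "ymid", "yamp", "gk", "masses", "sigma_f")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  if (identical(cfg$kind, "double_well"))
    return(make_double_well(cfg$delta_g_target, cfg$barrier, cfg$temperature))
  make_flip_model(delta_g_target = cfg$delta_g_target, barrier = cfg$barrier,
                  coupling = cfg$coupling,
                  ligand_strength = cfg$ligand_strength,
                  temperature = cfg$temperature, ymid = cfg$ymid,
                  yamp = cfg$yamp, gk = cfg$gk, masses = unlist(cfg$masses),
                  sigma_f = cfg$sigma_f)
}

#' Parse the coefficients back out of an exported PLUMED block
#' @param lines character vector as produced by \code{\link{export_plumed_cv}}
#' @return numeric coefficients
#' @export
parse_plumed_cv <- function(lines) {
  cl <- grep(": COMBINE ", lines, value = TRUE)
  if (length(cl) != 1) stop("no COMBINE line found")
  m <- regmatches(cl, regexec("COEFFICIENTS=([^ ]+)", cl))[[1]]
  as.numeric(strsplit(m[2], ",")[[1]])
}
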