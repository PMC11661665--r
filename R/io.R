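# Readers/writers for every external representation the framework touches:
# PQR / PDB-with-charges snapshots, oxDNA topology+configuration text files,
# per-frame hydrogen-bond pair lists, the engine's external-forces dialect and
# its key = value input file, and FASTA sequences.
#
# Index convention: everything exposed to analysis is 0-based. The oxDNA
# dialects are 0-based already; PDB/PQR serials are 1-based and remapped at
# this boundary. PDB/PQR coordinates are in Angstrom on disk and converted to
# nm on read.

#' Read a charged structure (PQR or PDB-with-charge-column)
#'
#' Parses one particle per ATOM/HETATM record. PQR is whitespace-delimited
#' with charge and radius as the last two fields; the PDB dialect reads the
#' partial charge from the B-factor column and must be requested explicitly.
#'
#' @param path path to the file.
#' @param dialect \code{"pqr"} (default) or \code{"pdb_charge_column"}.
#' @return a \code{\link{charge_distribution}} with coordinates in nm.
#' @export
read_charged_structure <- function(path, dialect = c("pqr", "pdb_charge_column")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop(sprintf("no ATOM/HETATM records in %s", path))
  pos <- matrix(NA_real_, length(idx), 3)
  q <- numeric(length(idx))
  labels <- character(length(idx))
  for (k in seq_along(idx)) {
    ln <- lines[idx[k]]
    lineno <- idx[k]
    if (dialect == "pqr") {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      # ATOM serial name resName [chain] resSeq x y z q r
      if (length(tok) < 10L)
        stop(sprintf("line %d: record has %d fields; no charge field present",
                     lineno, length(tok)))
      nums <- suppressWarnings(as.numeric(tok[(length(tok) - 4):length(tok)]))
      if (any(is.na(nums)))
        stop(sprintf("malformed PQR record at line %d: '%s'", lineno, ln))
      pos[k, ] <- nums[1:3]
      q[k] <- nums[4]
      labels[k] <- tok[3]
    } else {
      if (nchar(ln) < 66L)
        stop(sprintf("line %d: PDB record too short for a B-factor charge column; no charges", lineno))
      xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                           substr(ln, 47, 54))))
      bf <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
      if (any(is.na(xyz)))
        stop(sprintf("malformed PDB coordinates at line %d", lineno))
      if (is.na(bf))
        stop(sprintf("line %d: empty B-factor column; no charges", lineno))
      pos[k, ] <- xyz
      q[k] <- bf
      labels[k] <- trimws(substr(ln, 13, 16))
    }
  }
  charge_distribution(pos / 10, q, labels = labels)  # Angstrom -> nm
}

#' Write a charge distribution as a PQR file
#'
#' Coordinates are written in Angstrom with 6 decimals and charges with 6
#' decimals, so a write/read round trip reproduces positions within 1e-6 nm.
#'
#' @param dist a \code{\link{charge_distribution}} (nm).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pqr <- function(dist, path) {
  stopifnot(inherits(dist, "charge_distribution"))
  ang <- dist$positions * 10
  lab <- if (is.null(dist$labels)) rep("X", nrow(ang)) else dist$labels
  lines <- sprintf("ATOM  %5d %-4s %-4s %5d   %10.6f %10.6f %10.6f %9.6f %7.4f",
                   seq_len(nrow(ang)), substr(lab, 1, 4), "RES",
                   seq_len(nrow(ang)), ang[, 1], ang[, 2], ang[, 3],
                   dist$charges, 1.0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a coarse-grained chain from oxDNA topology + configuration files
#'
#' @param topology path to the topology file (strand/base/neighbour table).
#' @param configuration path to the configuration file (t/b/E header plus one
#'   row of position, orientation and velocity components per nucleotide).
#' @return a \code{\link{chain_conformation}} with positions in lambda_ox and
#'   the sequence taken from the topology.
#' @export
read_oxdna_chain <- function(topology, configuration) {
  top <- readLines(topology, warn = FALSE)
  head1 <- strsplit(trimws(top[1]), "\\s+")[[1]]
  n_top <- as.integer(head1[1])
  rows <- strsplit(trimws(top[-1]), "\\s+")
  rows <- rows[vapply(rows, length, 1L) >= 4L]
  if (length(rows) != n_top)
    stop(sprintf("topology declares %d nucleotides but lists %d", n_top, length(rows)))
  seq_letters <- vapply(rows, `[[`, "", 2L)
  neigh3 <- as.integer(vapply(rows, `[[`, "", 3L))
  circular <- !any(neigh3 == -1L)

  conf <- readLines(configuration, warn = FALSE)
  body <- conf[!grepl("^[tbE]\\s*=", conf)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_top)
    stop(sprintf("nucleotide count mismatch: topology has %d, configuration has %d",
                 n_top, length(body)))
  vals <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  pos <- t(vapply(vals, function(v) v[1:3], numeric(3)))
  chain_conformation(pos, sequence = seq_letters, circular = circular,
                     unit = "lambda_ox")
}

#' Write a chain in the oxDNA topology/configuration dialect
#'
#' Orientation vectors are written as canonical frames and velocities as zero;
#' only positions, sequence and connectivity carry information here.
#'
#' @param chain a \code{\link{chain_conformation}} in lambda_ox units.
#' @param topology,configuration output paths.
#' @return invisibly, a list with the two paths.
#' @export
write_oxdna_chain <- function(chain, topology, configuration) {
  stopifnot(inherits(chain, "chain_conformation"))
  if (chain$unit != "lambda_ox")
    stop("oxDNA files are written in lambda_ox units; convert first")
  n <- nrow(chain$positions)
  seq_letters <- if (is.null(chain$sequence)) rep("A", n) else chain$sequence
  i0 <- seq_len(n) - 1L
  n3 <- i0 - 1L; n5 <- i0 + 1L
  if (chain$circular) { n3[1] <- n - 1L; n5[n] <- 0L } else { n3[1] <- -1L; n5[n] <- -1L }
  writeLines(c(sprintf("%d %d", n, 1L),
               sprintf("%d %s %d %d", 1L, seq_letters, n3, n5)), topology)
  writeLines(c("t = 0",
               "b = 1000 1000 1000",
               "E = 0 0 0",
               sprintf("%.8f %.8f %.8f 1 0 0 0 1 0 0 0 0 0 0 0",
                       chain$positions[, 1], chain$positions[, 2],
                       chain$positions[, 3])), configuration)
  invisible(list(topology = topology, configuration = configuration))
}

#' Read per-frame hydrogen-bond pair lists
#'
#' The dialect is frame-delimited plain text: a line starting with
#' \code{# frame} (or \code{t =}) opens a frame, followed by one
#' whitespace-separated 0-based index pair per line. Pairs are stored
#' unordered as (min, max); duplicates collapse.
#'
#' @param path path to the pair-list file.
#' @param n optional chain length for range checking.
#' @return a list of \code{\link{hb_frame}} objects in file order.
#' @export
read_hb_frames <- function(path, n = NULL) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  cur <- NULL
  cur_idx <- -1L
  flush <- function() {
    if (!is.null(cur))
      frames[[length(frames) + 1L]] <<- hb_frame(cur_idx,
        if (length(cur)) do.call(rbind, cur) else matrix(integer(0), ncol = 2), n = n)
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (grepl("^#", t) || grepl("^t\\s*=", t)) {
      flush()
      m <- regmatches(t, regexpr("[0-9]+", t))
      cur_idx <- if (length(m)) as.integer(m) else cur_idx + 1L
      cur <- list()
    } else {
      if (is.null(cur)) { cur <- list(); cur_idx <- 0L }
      tok <- suppressWarnings(as.integer(strsplit(t, "\\s+")[[1]]))
      if (length(tok) < 2L || any(is.na(tok[1:2])))
        stop(sprintf("malformed pair line: '%s'", ln))
      cur[[length(cur) + 1L]] <- tok[1:2]
    }
  }
  flush()
  frames
}

#' Write hydrogen-bond frames in the frame-delimited pair-list dialect
#'
#' @param frames list of \code{\link{hb_frame}} objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hb_frames <- function(frames, path) {
  out <- character(0)
  for (f in frames) {
    out <- c(out, sprintf("# frame %d", f$frame_index))
    if (nrow(f$pairs))
      out <- c(out, sprintf("%d %d", f$pairs[, 1], f$pairs[, 2]))
  }
  writeLines(out, path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)  # round-trips doubles exactly

#' Export static potentials in the engine's external-forces dialect
#'
#' Writes a text file of brace-delimited force blocks. Supported descriptors:
#' a harmonic end-restraint between two nucleotides (\code{kind =
#' "end_restraint"}: fields \code{k}, \code{d0}, \code{i}, \code{j}), a static
#' radial wall (\code{kind = "static_wall"}: fields \code{R0}, \code{omega}),
#' and a tabulated radial potential (\code{kind = "tabulated"}: field
#' \code{profile}, a \code{\link{radial_potential_profile}}), which also emits
#' a two-column r/U table next to \code{path}. Time-dependent descriptors
#' (squeeze schedules) are rejected: express them as per-checkpoint static
#' files via \code{\link{plan_squeeze_checkpoints}}.
#'
#' @param specs list of descriptor lists.
#' @param path output path for the forces file.
#' @return invisibly, the paths written (forces file first).
#' @export
export_external_forces <- function(specs, path) {
  blocks <- character(0)
  written <- path
  tab_i <- 0L
  for (s in specs) {
    if (inherits(s, "squeeze_schedule") ||
        (!is.null(s$kind) && s$kind %in% c("squeeze", "time_dependent")))
      stop("time-dependent squeeze potential is not expressible as a static force file; use plan_squeeze_checkpoints()")
    kind <- s$kind
    if (identical(kind, "end_restraint")) {
      blocks <- c(blocks, "{", "type = mutual_trap",
                  sprintf("particle = %d", s$i),
                  sprintf("ref_particle = %d", s$j),
                  sprintf("stiff = %s", fmt_num(s$k)),
                  sprintf("r0 = %s", fmt_num(s$d0)),
                  "PBC = 0", "}")
    } else if (identical(kind, "static_wall")) {
      blocks <- c(blocks, "{", "type = sphere",
                  "particle = -1", "center = 0,0,0",
                  sprintf("stiff = %s", fmt_num(s$omega)),
                  sprintf("r0 = %s", fmt_num(s$R0)), "}")
    } else if (identical(kind, "tabulated")) {
      tab_i <- tab_i + 1L
      prof <- s$profile
      tab <- sub("(\\.[^.]*)?$", sprintf("_table%d.tsv", tab_i), path)
      writeLines(c("r\tU", sprintf("%s\t%s", fmt_num(prof$r), fmt_num(prof$U))), tab)
      blocks <- c(blocks, "{", "type = radial_table",
                  "particle = -1", "center = 0,0,0",
                  sprintf("table = %s", basename(tab)), "}")
      written <- c(written, tab)
    } else stop(sprintf("unknown force descriptor kind: %s", kind))
  }
  writeLines(blocks, path)
  invisible(written)
}

#' Re-parse an external-forces file written by \code{export_external_forces}
#'
#' @param path path to the forces file.
#' @return list of descriptor lists with numeric parameters restored
#'   bit-exactly.
#' @export
read_external_forces <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  specs <- list()
  cur <- NULL
  for (ln in lines) {
    if (ln == "{") { cur <- list() }
    else if (ln == "}") {
      kv <- cur
      spec <- switch(kv$type,
        mutual_trap = list(kind = "end_restraint",
                           i = as.integer(kv$particle),
                           j = as.integer(kv$ref_particle),
                           k = as.numeric(kv$stiff), d0 = as.numeric(kv$r0)),
        sphere = list(kind = "static_wall", omega = as.numeric(kv$stiff),
                      R0 = as.numeric(kv$r0)),
        radial_table = {
          tabpath <- file.path(dirname(path), kv$table)
          tab <- utils::read.delim(tabpath)
          list(kind = "tabulated",
               profile = radial_potential_profile(tab$r, tab$U, strict_zero = FALSE))
        },
        stop(sprintf("unknown force block type: %s", kv$type)))
      specs[[length(specs) + 1L]] <- spec
      cur <- NULL
    } else if (grepl("=", ln) && !is.null(cur)) {
      kv <- strsplit(ln, "\\s*=\\s*")[[1]]
      cur[[kv[1]]] <- kv[2]
    }
  }
  specs
}

#' Write an engine input file from a protocol configuration
#'
#' @param cfg an \code{\link{oxdna_protocol_config}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_oxdna_input <- function(cfg, path) {
  stopifnot(inherits(cfg, "oxdna_protocol_config"))
  lines <- c("backend = CPU",
             "sim_type = MD",
             sprintf("dt = %g", cfg$timestep),
             sprintf("steps = %d", as.integer(cfg$steps)),
             sprintf("T = %gK", cfg$temperature),
             sprintf("salt_concentration = %g", cfg$salt),
             "interaction_type = RNA2")
  if (cfg$thermostat == "bussi") {
    lines <- c(lines, "thermostat = bussi",
               sprintf("bussi_tau = %d", as.integer(cfg$bussi_correlation)),
               sprintf("newtonian_steps = %d", as.integer(cfg$bussi_frequency)))
  } else {
    lines <- c(lines, "thermostat = john",
               sprintf("diff_coeff = %g", cfg$langevin_diffusion),
               sprintf("newtonian_steps = %d", as.integer(cfg$langevin_frequency)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an RNA sequence from a FASTA file
#'
#' @param path path to a FASTA file with a single RNA record (T is accepted
#'   and read as U).
#' @return character vector of nucleotide letters (A/C/G/U).
#' @export
read_rna_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) != 1L) stop("expected a single FASTA record")
    s <- toupper(as.character(ss[[1]]))
  } else {
    lines <- readLines(path, warn = FALSE)
    s <- toupper(paste(lines[!grepl("^>", lines)], collapse = ""))
  }
  s <- chartr("T", "U", s)
  letters <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(letters), c("A", "C", "G", "U"))
  if (length(bad))
    stop(sprintf("non-RNA letters in sequence: %s", paste(bad, collapse = ", ")))
  letters
}
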