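## Extended-XYZ interchange: configurations with optional per-frame Wannier
## centres (pseudo-species "X"), forces, applied field and group id. Tabular
## output with unit-annotated headers.

parse_kv_line <- function(line) {
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|[^[:space:]]+)', line)
  toks <- regmatches(line, m)[[1]]
  out <- list()
  for (t in toks) {
    eq <- regexpr("=", t)
    key <- substr(t, 1, eq - 1)
    val <- substr(t, eq + 1, nchar(t))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

num_vec <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])

#' Read an extended-XYZ file
#'
#' Parses one or more frames. Rows with species `X` are interpreted as
#' Wannier centres and separated from the nuclei; they are assigned to the
#' nearest oxygen (exactly four per molecule required when present) and put
#' in canonical bond/lone order. Recognized comment-line keys: `Lattice`
#' (9 numbers, orthorhombic required), `Properties` (`pos` and optionally
#' `forces`), `applied_field` (V/Angstrom vector), `group_id`.
#'
#' @param path File path.
#' @return List of frames, each a list with `config`, `wannier` (or NULL),
#'   `forces` (or NULL), `applied_field`, `group_id`.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed atom-count line at line ", i)
    if (i + 1 + nat > length(lines))
      stop("truncated frame at line ", i)
    kv <- parse_kv_line(lines[i + 1])
    if (is.null(kv$Lattice)) stop("missing Lattice in frame header")
    lat <- num_vec(kv$Lattice)
    if (length(lat) != 9) stop("malformed Lattice line")
    M <- matrix(lat, 3, 3, byrow = TRUE)
    if (max(abs(M[upper.tri(M) | lower.tri(M)])) > 1e-10)
      stop("only orthorhombic lattices are supported")
    cl <- cell(diag(M))
    has_forces <- !is.null(kv$Properties) &&
      grepl("forces", kv$Properties, fixed = TRUE)
    body <- lines[(i + 2):(i + 1 + nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    sp <- vapply(toks, `[`, character(1), 1)
    nums <- t(vapply(toks, function(x) as.numeric(x[-1]),
                     numeric(if (has_forces) 6 else 3)))
    if (anyNA(nums)) stop("inconsistent columns in frame body")
    is_x <- sp == "X"
    config <- atomic_config(sp[!is_x], nums[!is_x, 1:3, drop = FALSE], cl)
    forces <- if (has_forces) nums[!is_x, 4:6, drop = FALSE] else NULL
    wann <- NULL
    if (any(is_x)) {
      wann <- assign_centers(config, nums[is_x, 1:3, drop = FALSE])
    }
    frames[[length(frames) + 1L]] <- list(
      config = config, wannier = wann, forces = forces,
      applied_field = if (is.null(kv$applied_field)) c(0, 0, 0)
                      else num_vec(kv$applied_field),
      group_id = if (is.null(kv$group_id)) length(frames) + 1L
                 else as.integer(kv$group_id))
    i <- i + 2 + nat
  }
  frames
}

# assign free centres to molecules (nearest O) and order them canonically
assign_centers <- function(config, xpos, params = oracle_params()) {
  mols <- detect_water_topology(config)
  n_mol <- nrow(mols)
  if (nrow(xpos) != 4 * n_mol)
    stop("need exactly 4 Wannier centres per molecule, got ",
         nrow(xpos), " for ", n_mol, " molecules")
  o_pos <- config$positions[mols$o, , drop = FALSE]
  near <- integer(nrow(xpos))
  for (i in seq_len(nrow(xpos))) {
    d <- minimum_image(sweep(o_pos, 2, xpos[i, ], "-"), config$cell)
    near[i] <- which.min(rowSums(d^2))
  }
  if (any(table(factor(near, levels = seq_len(n_mol))) != 4))
    stop("Wannier centres do not partition into 4 per molecule")
  pos <- matrix(0, 4 * n_mol, 3)
  for (m in seq_len(n_mol)) {
    cm <- xpos[near == m, , drop = FALSE]
    ord <- match_centers(cm, mols[m, ], config, params)$order
    pos[(4 * m - 3):(4 * m), ] <- cm[ord, ]
  }
  wannier_set(pos, rep(seq_len(n_mol), each = 4))
}

#' Write frames to an extended-XYZ file
#'
#' @param frames A single frame (list with `config` and optionally `wannier`,
#'   `forces`, `applied_field`, `group_id`) or a list of such frames; a bare
#'   [atomic_config()] is also accepted.
#' @param path Output path.
#' @export
write_extxyz <- function(frames, path) {
  if (inherits(frames, "atomic_config")) frames <- list(list(config = frames))
  if (!is.null(frames$config)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    config <- fr$config
    nw <- if (is.null(fr$wannier)) 0 else nrow(fr$wannier$positions)
    has_forces <- !is.null(fr$forces)
    L <- config$cell$lengths
    props <- if (has_forces) "species:S:1:pos:R:3:forces:R:3"
             else "species:S:1:pos:R:3"
    hdr <- sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=%s',
                   L[1], L[2], L[3], props)
    if (!is.null(fr$applied_field))
      hdr <- paste0(hdr, sprintf(' applied_field="%.10g %.10g %.10g"',
                                 fr$applied_field[1], fr$applied_field[2],
                                 fr$applied_field[3]))
    if (!is.null(fr$group_id))
      hdr <- paste0(hdr, sprintf(" group_id=%d", as.integer(fr$group_id)))
    writeLines(as.character(nrow(config$positions) + nw), con)
    writeLines(hdr, con)
    for (i in seq_len(nrow(config$positions))) {
      row <- sprintf("%.17g", config$positions[i, ])
      if (has_forces) row <- c(row, sprintf("%.17g", fr$forces[i, ]))
      writeLines(paste(config$species[i], paste(row, collapse = " ")), con)
    }
    if (nw > 0) {
      for (i in seq_len(nw)) {
        row <- sprintf("%.17g", fr$wannier$positions[i, ])
        if (has_forces) row <- c(row, "0 0 0")
        writeLines(paste("X", paste(row, collapse = " ")), con)
      }
    }
  }
  invisible(path)
}

#' Read a grouped training set from extended-XYZ
#'
#' @param path File written by [write_training_xyz()] (frames with centres,
#'   forces, applied field and group id).
#' @return List of training samples compatible with [scfnn()].
#' @export
read_training_xyz <- function(path) {
  frames <- read_extxyz(path)
  lapply(frames, function(fr) {
    if (is.null(fr$wannier))
      stop("training frames must carry Wannier centres (species X)")
    structure(list(config = fr$config, applied_field = fr$applied_field,
                   wannier = fr$wannier, forces = fr$forces,
                   group_id = fr$group_id),
              class = "training_sample")
  })
}

#' @rdname read_training_xyz
#' @param samples List of training samples (e.g. an `oracle_dataset`).
#' @export
write_training_xyz <- function(samples, path) {
  write_extxyz(lapply(samples, function(s)
    list(config = s$config, wannier = s$wannier, forces = s$forces,
         applied_field = s$applied_field, group_id = s$group_id)), path)
}

#' Write a correlation curve or profile as annotated text
#'
#' Tab-separated columns preceded by `#` header lines declaring the
#' observable and the column units; numeric round trip is exact to within
#' double formatting (17 significant digits).
#'
#' @param curve A `correlation_curve` or any data.frame.
#' @param path Output path.
#' @export
write_table <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  obs <- attr(curve, "observable")
  if (!is.null(obs)) writeLines(paste("#", obs), con)
  ab <- attr(curve, "abscissa")
  writeLines(paste0("# columns: ", paste(names(curve), collapse = "\t"),
                    if (!is.null(ab)) paste0("  (abscissa: ", ab, ")") else ""),
             con)
  if (nrow(curve))
    utils::write.table(format(curve, digits = 17, trim = TRUE), con,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}
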