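# Minimal DICOM codec: part-10 files, explicit and implicit VR little endian,
# nested sequences.  Only what CT image and RT Structure Set objects need.
# Elements are held in named lists keyed "GGGGEEEE" (uppercase hex).

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_IMAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_IMPL_CLASS <- "1.2.826.0.1.3680043.9.7435.1"

# VR lookup for implicit-VR parsing: the tags this package reads or writes.
DCM_DICT <- c(
  "00020002" = "UI", "00020003" = "UI", "00020010" = "UI", "00020012" = "UI",
  "00080005" = "CS", "00080016" = "UI", "00080018" = "UI", "00080020" = "DA",
  "00080030" = "TM", "00080050" = "SH", "00080060" = "CS", "00080070" = "LO",
  "00081150" = "UI", "00081155" = "UI",
  "00100010" = "PN", "00100020" = "LO",
  "0020000D" = "UI", "0020000E" = "UI", "00200011" = "IS", "00200013" = "IS",
  "00200032" = "DS", "00200037" = "DS", "00200052" = "UI",
  "00280002" = "US", "00280004" = "CS", "00280010" = "US", "00280011" = "US",
  "00280030" = "DS", "00280100" = "US", "00280101" = "US", "00280102" = "US",
  "00280103" = "US", "00281052" = "DS", "00281053" = "DS",
  "00180050" = "DS",
  "30060002" = "SH", "30060010" = "SQ", "30060012" = "SQ", "30060014" = "SQ",
  "30060016" = "SQ", "30060020" = "SQ", "30060022" = "IS", "30060024" = "UI",
  "30060026" = "LO", "30060036" = "CS", "30060039" = "SQ", "3006002A" = "IS",
  "30060040" = "SQ", "30060042" = "CS", "30060046" = "IS", "30060050" = "DS",
  "30060080" = "SQ", "30060082" = "IS", "30060084" = "IS", "300600A4" = "CS",
  "7FE00010" = "OW"
)

STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
                "TM", "UI", "UC", "UR", "UT")
LONG_LEN_VRS <- c("OB", "OW", "OF", "SQ", "UN", "UT", "UC", "UR")

tag_key <- function(group, element) sprintf("%04X%04X", group, element)

uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32 <- function(x) {
  # R integers are signed 32-bit; lengths here never exceed 2^31-1
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

fmt_ds <- function(x) {
  s <- sprintf("%.6f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

dcm_encode_value <- function(vr, value) {
  if (vr %in% STRING_VRS) {
    s <- paste(as.character(value), collapse = "\\")
    v <- charToRaw(s)
    if (length(v) %% 2 == 1)
      v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
    return(v)
  }
  switch(vr,
    DS = dcm_encode_value("LO", fmt_ds(value)),
    IS = dcm_encode_value("LO", as.character(as.integer(value))),
    US = uint16(value),
    UL = uint32(value),
    SS = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    SL = uint32(value),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    OB = ,
    OW = as.raw(value),
    stop("unsupported VR for encoding: ", vr)
  )
}

# One data element, explicit VR little endian.  For SQ, `value` is a list of
# raw vectors (already-encoded item datasets); written with undefined length.
dcm_element <- function(group, element, vr, value) {
  tag <- c(uint16(group), uint16(element))
  if (vr == "SQ") {
    items <- lapply(value, function(item)
      c(uint16(0xFFFE), uint16(0xE000), uint32(length(item)), item))
    body <- do.call(c, c(items, list(raw(0))))
    return(c(tag, charToRaw("SQ"), raw(2), as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)),
             body, uint16(0xFFFE), uint16(0xE0DD), uint32(0)))
  }
  v <- dcm_encode_value(vr, value)
  if (vr %in% LONG_LEN_VRS)
    c(tag, charToRaw(vr), raw(2), uint32(length(v)), v)
  else
    c(tag, charToRaw(vr), uint16(length(v)), v)
}

# Assemble and write a part-10 file.  `dataset` is a raw vector of encoded
# elements (caller is responsible for tag ordering).
dcm_write_file <- function(path, sop_class_uid, sop_instance_uid, dataset) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", c(0x00, 0x01)),
    dcm_element(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", UID_IMPL_CLASS)
  )
  header <- c(raw(128), charToRaw("DICM"),
              dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, dataset), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# reading
# ---------------------------------------------------------------------------

r_uint16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1])
}
r_uint32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1]) +
    65536 * as.numeric(raw[pos + 2]) + 16777216 * as.numeric(raw[pos + 3])
}

decode_string <- function(bytes) {
  s <- rawToChar(bytes[bytes != as.raw(0)])
  sub(" +$", "", s)
}

dcm_decode_value <- function(vr, bytes) {
  if (vr %in% STRING_VRS) {
    parts <- strsplit(decode_string(bytes), "\\", fixed = TRUE)[[1]]
    if (vr == "DS") return(as.numeric(parts))
    return(parts)
  }
  switch(vr,
    DS = as.numeric(strsplit(decode_string(bytes), "\\", fixed = TRUE)[[1]]),
    IS = as.integer(strsplit(decode_string(bytes), "\\", fixed = TRUE)[[1]]),
    US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    SS = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = TRUE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    SL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FL = readBin(bytes, "numeric", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FD = readBin(bytes, "numeric", n = length(bytes) / 8, size = 8,
                 endian = "little"),
    bytes # OB/OW/UN: raw passthrough
  )
}

# Parse elements in raw[pos..end] (1-based, inclusive); returns
# list(elements = named list, pos = next position).  Stops at `end`, at an
# item delimitation tag, or (top level) never early.
dcm_parse <- function(raw, pos, end, explicit) {
  out <- list()
  while (pos + 7 <= end + 1 && pos <= end) {
    group <- r_uint16(raw, pos)
    element <- r_uint16(raw, pos + 2)
    pos <- pos + 4
    if (group == 0xFFFE) {
      len <- r_uint32(raw, pos); pos <- pos + 4
      if (element == 0xE00D || element == 0xE0DD)
        return(list(elements = out, pos = pos, delim = element))
      stop("unexpected item tag outside sequence")
    }
    key <- tag_key(group, element)
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1)]); pos <- pos + 2
      if (vr %in% LONG_LEN_VRS) {
        len <- r_uint32(raw, pos + 2); pos <- pos + 6
      } else {
        len <- r_uint16(raw, pos); pos <- pos + 2
      }
    } else {
      vr <- if (key %in% names(DCM_DICT)) DCM_DICT[[key]] else "UN"
      len <- r_uint32(raw, pos); pos <- pos + 4
    }
    if (vr == "SQ" || (len == 4294967295 && vr %in% c("UN", "OB", "OW"))) {
      sq <- dcm_parse_sequence(raw, pos, end, len, explicit)
      out[[key]] <- sq$items
      pos <- sq$pos
    } else {
      if (len == 4294967295) stop("undefined length on non-sequence element ", key)
      bytes <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
      out[[key]] <- dcm_decode_value(vr, bytes)
      pos <- pos + len
    }
  }
  list(elements = out, pos = pos, delim = NA)
}

dcm_parse_sequence <- function(raw, pos, end, len, explicit) {
  items <- list()
  sq_end <- if (len != 4294967295) pos + len - 1 else end
  repeat {
    if (pos + 7 > sq_end + 1 || pos > sq_end) break
    group <- r_uint16(raw, pos); element <- r_uint16(raw, pos + 2)
    ilen <- r_uint32(raw, pos + 4)
    pos <- pos + 8
    if (group != 0xFFFE) stop("malformed sequence item tag")
    if (element == 0xE0DD) break
    if (element != 0xE000) stop("malformed sequence item")
    if (ilen != 4294967295) {
      parsed <- dcm_parse(raw, pos, pos + ilen - 1, explicit)
      items[[length(items) + 1]] <- parsed$elements
      pos <- pos + ilen
    } else {
      parsed <- dcm_parse(raw, pos, sq_end, explicit)
      items[[length(items) + 1]] <- parsed$elements
      pos <- parsed$pos
      if (is.na(parsed$delim) || parsed$delim != 0xE00D)
        stop("unterminated sequence item")
    }
  }
  list(items = items, pos = pos)
}

# Read a DICOM file into list(meta =, data =, transfer_syntax =).
dcm_read_file <- function(path) {
  n <- file.info(path)$size
  raw <- readBin(path, "raw", n = n)
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133
  } else {
    # headerless stream; sniff explicit VR from bytes 5-6
    vr <- rawToChar(raw[5:6])
    explicit <- vr %in% c(STRING_VRS, LONG_LEN_VRS, "US", "UL", "SS", "SL",
                          "FL", "FD", "DS", "IS", "SQ")
    d <- dcm_parse(raw, 1, length(raw), explicit)
    return(list(meta = list(), data = d$elements,
                transfer_syntax = if (explicit) UID_EXPLICIT_LE else UID_IMPLICIT_LE))
  }
  # file meta group is always explicit VR LE
  m0 <- dcm_parse(raw, pos, pos + 11, TRUE) # (0002,0000) group length
  glen <- m0$elements[["00020000"]]
  meta <- dcm_parse(raw, m0$pos, m0$pos + glen - 1, TRUE)
  ts <- meta$elements[["00020010"]]
  if (is.null(ts)) ts <- UID_EXPLICIT_LE
  explicit <- !identical(ts, UID_IMPLICIT_LE)
  d <- dcm_parse(raw, meta$pos, length(raw), explicit)
  list(meta = meta$elements, data = d$elements, transfer_syntax = ts)
}

# Deterministic-under-seed UID generation from R's RNG, under a fixed root.
oar_uid <- function(n = 1, root = getOption("oarseg.uid_root", "2.25.")) {
  vapply(seq_len(n), function(i) {
    digits <- paste(sample.int(10, 30, replace = TRUE) - 1L, collapse = "")
    digits <- sub("^0+", "", digits)
    if (nchar(digits) == 0) digits <- "7"
    paste0(root, digits)
  }, character(1))
}
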