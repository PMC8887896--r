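# Internal helpers shared across modules.

# Study-site local time is a fixed UTC+3 offset; "Etc/GMT-3" is POSIX sign
# convention for UTC+3.
ACC_TZ <- "Etc/GMT-3"

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package functions never perturb the global
#' random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stage label, kept within
# 32-bit integer range.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# "HH:MM" -> minutes since local midnight
hm_to_min <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(parts[1]) * 60 + as.numeric(parts[2])
}

# minutes since local midnight -> "HH:MM"
min_to_hm <- function(m) {
  m <- ((m %% 1440) + 1440) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

# POSIXct at local midnight of `date` (a Date) in study-site time
local_midnight <- function(date) {
  as.POSIXct(paste0(format(date), " 00:00:00"), tz = ACC_TZ)
}

# Minute-of-day (0..1439) of a POSIXct in study-site time
minute_of_day <- function(time) {
  lt <- as.POSIXlt(time, tz = ACC_TZ)
  lt$hour * 60 + lt$min
}

# Local equirectangular projection (meters) about a reference lon/lat.
# Adequate for site extents of a few km; metric thresholds (5 m, 10 m) in
# the pipeline are evaluated in this projection.
local_project <- function(lon, lat, ref_lon, ref_lat) {
  m_per_deg <- 111194.9  # mean earth radius * pi / 180
  list(
    x = (lon - ref_lon) * m_per_deg * cos(ref_lat * pi / 180),
    y = (lat - ref_lat) * m_per_deg
  )
}

local_unproject <- function(x, y, ref_lon, ref_lat) {
  m_per_deg <- 111194.9
  list(
    lon = ref_lon + x / (m_per_deg * cos(ref_lat * pi / 180)),
    lat = ref_lat + y / m_per_deg
  )
}

# Maximal runs of TRUE in a logical vector (NA treated as FALSE).
# Returns data.frame(start, end, length); zero rows when none.
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start = starts[keep],
    end = ends[keep],
    length = r$lengths[keep]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse file timestamps as site-local wall time. CSV readers that
# auto-parse ISO-8601 assume UTC, so already-parsed POSIXct columns are
# reinterpreted by their wall-clock representation.
parse_local_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    x <- format(x, "%Y-%m-%d %H:%M:%OS6", tz = "UTC")
  }
  out <- as.POSIXct(x, tz = ACC_TZ,
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(out)) {
    stop(sprintf("unparseable timestamp '%s'", x[which(is.na(out))[1]]),
         call. = FALSE)
  }
  out
}
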