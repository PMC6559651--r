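# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the code paths (and helper libraries) the
# package itself uses.

# brute-force piecewise-linear interpolation: locate the segment by scan,
# interpolate with the two-point line formula
oracle_interp <- function(xs, sis, x) {
  vapply(x, function(xx) {
    if (xx <= xs[1]) return(sis[1])
    n <- length(xs)
    if (xx >= xs[n]) return(sis[n])
    for (i in seq_len(n - 1)) {
      if (xx >= xs[i] && xx <= xs[i + 1]) {
        w <- (xx - xs[i]) / (xs[i + 1] - xs[i])
        return((1 - w) * sis[i] + w * sis[i + 1])
      }
    }
    stop("unreachable")
  }, numeric(1))
}

# haversine great-circle distance written out from the formula
oracle_haversine_km <- function(lon1, lat1, lon2, lat2, R = 6371.0088) {
  torad <- pi / 180
  dlat <- (lat2 - lat1) * torad
  dlon <- (lon2 - lon1) * torad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * torad) * cos(lat2 * torad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# full HSI recomputation from raw records: independent aggregation,
# curve evaluation and component-index algebra
oracle_hsi <- function(records, curveset, weight_mode = "normalized") {
  ev <- function(id, x) {
    bp <- curveset[[id]]$breakpoints
    oracle_interp(bp$x, bp$si, x)
  }
  cols <- c(temperature = "temp_c", salinity = "salinity_ppt",
            do_sat = "do_pct_sat", ph = "ph", chla = "chla_ug_l",
            pim = "pim_mg_l", velocity = "velocity_m_s")
  out <- numeric(0)
  for (st in unique(records$station_id)) {
    sub <- records[records$station_id == st, ]
    # collapse station-date duplicates, then split by calendar season
    key <- paste(sub$station_id, sub$date)
    daily <- do.call(rbind, lapply(unique(key), function(k) {
      g <- sub[key == k, ]
      d <- g[1, ]
      for (cn in cols) d[[cn]] <- mean(g[[cn]])
      d
    }))
    mth <- as.integer(format(as.Date(daily$date), "%m"))
    seas <- function(rows) {
      sapply(unname(cols), function(cn) mean(rows[[cn]]))
    }
    mu_m <- seas(daily[mth %in% 6:9, ])
    mu_nm <- seas(daily[!(mth %in% 6:9), ])
    si <- function(mu) c(
      Ss = ev("Ss", mu[["salinity_ppt"]]), V = ev("V", mu[["velocity_m_s"]]),
      T = ev("T", mu[["temp_c"]]), Sg = ev("S_G", mu[["salinity_ppt"]]),
      pH = ev("pH", mu[["ph"]]), DO = ev("DO", mu[["do_pct_sat"]]),
      PIM = ev("PIM", mu[["pim_mg_l"]]), Chla = ev("Chla", mu[["chla_ug_l"]]))
    sm <- si(mu_m); snm <- si(mu_nm)
    ci_set <- ((sm[["Ss"]] * sm[["V"]])^0.5 + (snm[["Ss"]] * snm[["V"]])^0.5) / 2
    post6 <- function(s) (s[["T"]] * s[["Sg"]] * s[["pH"]] * s[["DO"]] *
                            s[["PIM"]] * s[["Chla"]])^(1 / 6)
    e <- if (weight_mode == "normalized") c(4 / 12, 8 / 12) else c(1 / 3, 1 / 3)
    ci_post <- post6(sm)^e[1] * post6(snm)^e[2]
    hsi <- if (ci_post < ci_set) ci_post else sqrt(ci_post * ci_set)
    out[st] <- hsi
  }
  out
}

# one synthetic record builder for hand-made station fixtures
env_record <- function(station_id, date, temp = 28, sal = 25, do = 80,
                       ph = 8.1, chla = 5, pim = 100, vel = 0.4,
                       lon = 92, lat = 21.5) {
  data.frame(station_id = station_id, lon = lon, lat = lat,
             date = as.Date(date), temp_c = temp, salinity_ppt = sal,
             do_pct_sat = do, ph = ph, chla_ug_l = chla, pim_mg_l = pim,
             velocity_m_s = vel, stringsAsFactors = FALSE)
}

# records for one station whose seasonal means equal the supplied values
# exactly: every monsoon record carries the monsoon mean, etc.
station_records <- function(station_id, means_m, means_nm,
                            n_m = 4, n_nm = 3) {
  dm <- as.Date(sprintf("2016-%02d-15", 6:9))[seq_len(n_m)]
  dn <- as.Date(sprintf("2016-%02d-15", c(1, 5, 11)))[seq_len(n_nm)]
  rbind(
    do.call(rbind, lapply(dm, function(d)
      env_record(station_id, d, means_m[["temperature"]],
                 means_m[["salinity"]], means_m[["do_sat"]],
                 means_m[["ph"]], means_m[["chla"]], means_m[["pim"]],
                 means_m[["velocity"]]))),
    do.call(rbind, lapply(dn, function(d)
      env_record(station_id, d, means_nm[["temperature"]],
                 means_nm[["salinity"]], means_nm[["do_sat"]],
                 means_nm[["ph"]], means_nm[["chla"]], means_nm[["pim"]],
                 means_nm[["velocity"]]))))
}
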