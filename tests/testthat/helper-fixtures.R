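# Fixture builders used across test files. All data is generated in code.

# random undirected weighted graph on n nodes with m edges
rand_graph <- function(n, m, connected = FALSE) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  stopifnot(m <= nrow(pairs))
  if (connected) {
    perm <- sample(n)
    tree <- cbind(perm[-n], perm[-1])
    tree <- t(apply(tree, 1, sort))
    key <- paste(pairs[, 1], pairs[, 2])
    tkey <- paste(tree[, 1], tree[, 2])
    stopifnot(m >= n - 1)
    extra <- sample(which(!key %in% tkey), m - (n - 1))
    sel <- rbind(tree, pairs[extra, , drop = FALSE])
  } else {
    sel <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  }
  data.frame(source = nodes[sel[, 1]], target = nodes[sel[, 2]],
             weight = stats::runif(m, 0.05, 1), stringsAsFactors = FALSE)
}

rand_network <- function(n, m, connected = FALSE) {
  spatial_network(rand_graph(n, m, connected), nodes = sprintf("v%02d", seq_len(n)))
}

make_daily_panel <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  readings_panel(values, seq(as.Date("2021-01-01"), by = "day",
                             length.out = nrow(values)), "daily")
}

# Per-node (degree, weighted degree, global and composite influence) figures
# for two published urban-agglomeration rankings, used as closed-form
# consistency fixtures for the score wiring: W_LI must equal dw/n and W_LGI
# must equal (dw/n) * W_GI at printed precision.
pearl_delta_rows <- function() {
  data.frame(
    node = c("Guangzhou", "Shenzhen", "Zhuhai", "Dongguan", "Foshan",
             "Zhongshan", "Huizhou", "Jiangmen", "Zhaoqing"),
    dw   = c(2.036, 0.899, 1.172, 1.402, 2.384, 2.026, 1.125, 2.132, 0.488),
    W_LI = c(0.226, 0.100, 0.131, 0.156, 0.265, 0.225, 0.125, 0.237, 0.054),
    W_GI = c(8.743, 9.006, 9.207, 8.646, 8.774, 8.825, 10.104, 9.038, 8.395),
    W_LGI = c(1.978, 0.899, 1.199, 1.347, 2.324, 1.986, 1.263, 2.141, 0.456),
    n = 9, stringsAsFactors = FALSE)
}

yangtze_delta_rows <- function() {
  data.frame(
    node = c("Shanghai", "Nanjing", "Wuxi", "Changzhou", "Suzhou", "Nantong",
             "Yancheng", "Yangzhou", "Zhenjiang", "Taizhou_JS", "Hangzhou",
             "Ningbo", "Jiaxing", "Huzhou", "Shaoxing", "Jinhua", "Zhoushan",
             "Taizhou_ZJ", "Hefei", "Wuhu", "Maanshan", "Tongling", "Anqing",
             "Chuzhou", "Chizhou", "Xuancheng"),
    dw   = c(1.767, 3.465, 3.487, 3.297, 3.206, 2.134, 0.749, 3.469, 3.771,
             2.669, 2.409, 1.628, 2.723, 2.634, 2.092, 0.473, 0.551, 0.353,
             1.642, 3.093, 3.361, 2.123, 1.430, 2.306, 1.843, 1.817),
    W_LI = c(0.068, 0.133, 0.134, 0.127, 0.123, 0.082, 0.029, 0.133, 0.145,
             0.103, 0.093, 0.063, 0.105, 0.101, 0.080, 0.018, 0.021, 0.014,
             0.063, 0.119, 0.129, 0.082, 0.055, 0.089, 0.071, 0.070),
    W_GI = c(38.689, 38.834, 37.861, 37.952, 37.799, 37.856, 37.706, 37.517,
             38.164, 36.753, 38.963, 38.115, 38.117, 37.543, 39.143, 36.987,
             35.639, 36.554, 38.709, 38.365, 38.218, 37.646, 38.178, 37.740,
             37.474, 37.169),
    W_LGI = c(2.629, 5.176, 5.078, 4.813, 4.661, 3.108, 1.086, 5.006, 5.535,
              3.773, 3.610, 2.386, 3.993, 3.808, 3.150, 0.673, 0.756, 0.496,
              2.444, 4.564, 4.941, 3.073, 2.099, 3.348, 2.657, 2.597),
    n = 26, stringsAsFactors = FALSE)
}

# 12-station city monitoring fixture (ids, names, coordinates, type)
station_sites_csv <- function(path) {
  writeLines(c(
    "site_id,name,latitude,longitude,category",
    "1001A,Wanshouxigong,39.867,116.366,Urban",
    "1002A,Dingling,40.286,116.170,Suburban",
    "1003A,Dongsi,39.952,116.434,Urban",
    "1004A,Tiantan,39.874,116.434,Urban",
    "1005A,Nongzhanguan,39.972,116.473,Urban",
    "1006A,Guanyuan,39.942,116.361,Urban",
    "1007A,Haidianquwanliu,39.993,116.315,Urban",
    "1008A,Shunyixincheng,40.144,116.720,Suburban",
    "1009A,Huairouzhen,40.394,116.644,Suburban",
    "1010A,Changpingzhen,40.195,116.230,Suburban",
    "1011A,Aotizhongxin,40.003,116.407,Urban",
    "1012A,Gucheng,39.928,116.22,Urban"), path)
  path
}
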