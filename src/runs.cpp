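// Directional run statistics for binarized factorial response matrices, plus
// an independent brute-force categorizer used as an exhaustive cross-check.
//
// For each direction (row, column, diagonal, reverse diagonal) three
// statistics feed the decision rule: the longest run of consecutive active
// cells, the number of active cells NOT belonging to any run of at least
// min_run cells in that direction ("violations"), and the number of lines of
// that direction containing at least one active cell.
//
// Two implementations coexist on purpose:
//  * run_stats_scan(): line-scan (rle-style) counting used by the package's
//    categorizer (the R-level decision rule sits on top of these stats);
//  * oracle_*(): an independent per-cell neighbour-walking enumeration with
//    the decision rule re-coded in C++, so the two routes share no code.
#include <Rcpp.h>
using namespace Rcpp;

struct DirStats { int run, viol, lines; };
struct RunStats { DirStats d[4]; int active; };

// ---- implementation route: scan each line of each direction --------------
// Directions indexed: 0 row (horizontal), 1 column (vertical),
// 2 diagonal (down-right), 3 reverse diagonal (down-left).
static void scan_line(const int* b, int nr, int nc, int i0, int j0,
                      int di, int dj, int min_run, DirStats& s) {
  int i = i0, j = j0, run = 0, any = 0;
  while (i >= 0 && i < nr && j >= 0 && j < nc) {
    if (b[i + j * nr]) {
      ++run; any = 1;
    } else {
      if (run > s.run) s.run = run;
      if (run > 0 && run < min_run) s.viol += run;
      run = 0;
    }
    i += di; j += dj;
  }
  if (run > s.run) s.run = run;
  if (run > 0 && run < min_run) s.viol += run;
  s.lines += any;
}

static RunStats run_stats_scan(const int* b, int nr, int nc, int min_run) {
  RunStats s = {{{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {0, 0, 0}}, 0};
  for (int i = 0; i < nr * nc; ++i) s.active += (b[i] != 0);
  for (int i = 0; i < nr; ++i)
    scan_line(b, nr, nc, i, 0, 0, 1, min_run, s.d[0]);       // rows
  for (int j = 0; j < nc; ++j)
    scan_line(b, nr, nc, 0, j, 1, 0, min_run, s.d[1]);       // columns
  for (int j0 = -(nr - 1); j0 < nc; ++j0)                    // down-right
    scan_line(b, nr, nc, j0 < 0 ? -j0 : 0, j0 < 0 ? 0 : j0, 1, 1,
              min_run, s.d[2]);
  for (int j0 = 0; j0 < nc + nr - 1; ++j0)                   // down-left
    scan_line(b, nr, nc, j0 < nc ? 0 : j0 - nc + 1,
              j0 < nc ? j0 : nc - 1, 1, -1, min_run, s.d[3]);
  return s;
}

static IntegerVector stats_vector(const RunStats& s) {
  IntegerVector out(13);
  const char* dn[4] = {"row", "col", "diag", "anti"};
  CharacterVector nm(13);
  for (int d = 0; d < 4; ++d) {
    out[3 * d] = s.d[d].run; out[3 * d + 1] = s.d[d].viol;
    out[3 * d + 2] = s.d[d].lines;
    nm[3 * d] = std::string(dn[d]) + "_run";
    nm[3 * d + 1] = std::string(dn[d]) + "_viol";
    nm[3 * d + 2] = std::string(dn[d]) + "_lines";
  }
  out[12] = s.active; nm[12] = "n_active";
  out.names() = nm;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_run_stats(IntegerMatrix b, int min_run = 3) {
  return stats_vector(run_stats_scan(b.begin(), b.nrow(), b.ncol(), min_run));
}

// Run stats for every binary 5x4 matrix (bit i of id = cell i, column-major).
// [[Rcpp::export]]
IntegerMatrix cpp_run_stats_all5x4(int min_run = 3) {
  const int n = 1 << 20;
  IntegerMatrix out(n, 13);
  int b[20];
  for (int id = 0; id < n; ++id) {
    for (int i = 0; i < 20; ++i) b[i] = (id >> i) & 1;
    RunStats s = run_stats_scan(b, 5, 4, min_run);
    for (int d = 0; d < 4; ++d) {
      out(id, 3 * d) = s.d[d].run; out(id, 3 * d + 1) = s.d[d].viol;
      out(id, 3 * d + 2) = s.d[d].lines;
    }
    out(id, 12) = s.active;
  }
  colnames(out) = CharacterVector::create(
    "row_run", "row_viol", "row_lines", "col_run", "col_viol", "col_lines",
    "diag_run", "diag_viol", "diag_lines", "anti_run", "anti_viol",
    "anti_lines", "n_active");
  return out;
}

// ---- oracle route: per-cell walks + rule in C++ --------------------------
static int walk(const int* b, int nr, int nc, int i, int j, int di, int dj) {
  int len = 0;
  while (i >= 0 && i < nr && j >= 0 && j < nc && b[i + j * nr]) {
    ++len; i += di; j += dj;
  }
  return len;
}

// Through-cell run length = forward walk + backward walk - 1.
static int thru(const int* b, int nr, int nc, int i, int j, int di, int dj) {
  return walk(b, nr, nc, i, j, di, dj) +
         walk(b, nr, nc, i, j, -di, -dj) - 1;
}

// Is direction d a valid claim for this matrix? Recomputes everything by
// per-cell enumeration: longest through-cell run, count of active cells
// whose through-run is below min_run, and occupied-line count via flags.
static bool dir_valid(const int* b, int nr, int nc, int di, int dj,
                      int n_lines_all, int min_run, int max_stray) {
  int best = 0, viol = 0;
  bool occ[16];
  for (int i = 0; i < n_lines_all; ++i) occ[i] = false;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!b[i + j * nr]) continue;
      int r = thru(b, nr, nc, i, j, di, dj);
      if (r > best) best = r;
      if (r < min_run) ++viol;
      int line;
      if (di == 0) line = i;                 // row direction: line = row
      else if (dj == 0) line = j;            // column direction: line = col
      else if (dj == 1) line = j - i + nr - 1; // down-right: offset j - i
      else line = i + j;                     // down-left: offset i + j
      occ[line] = true;
    }
  int lines = 0;
  for (int i = 0; i < n_lines_all; ++i) lines += occ[i];
  return best >= min_run && viol <= max_stray && lines < n_lines_all;
}

// codes: 0 mixed, 1 ordinal, 2 retinotopic, 3 word_position
static int oracle_categorize(const int* b, int nr, int nc,
                             int min_run, int max_stray) {
  int active = 0;
  for (int i = 0; i < nr * nc; ++i) active += (b[i] != 0);
  if (active == 0) return 0;
  if (dir_valid(b, nr, nc, 1, 0, nc, min_run, max_stray)) return 1;
  if (dir_valid(b, nr, nc, 1, 1, nr + nc - 1, min_run, max_stray) ||
      dir_valid(b, nr, nc, 1, -1, nr + nc - 1, min_run, max_stray)) return 2;
  if (dir_valid(b, nr, nc, 0, 1, nr, min_run, max_stray)) return 3;
  return 0;
}

// [[Rcpp::export]]
int cpp_oracle_categorize(IntegerMatrix b, int min_run = 3,
                          int max_stray = 1) {
  return oracle_categorize(b.begin(), b.nrow(), b.ncol(), min_run, max_stray);
}

// [[Rcpp::export]]
IntegerVector cpp_oracle_categorize_all5x4(int min_run = 3,
                                           int max_stray = 1) {
  const int n = 1 << 20;
  IntegerVector out(n);
  int b[20];
  for (int id = 0; id < n; ++id) {
    for (int i = 0; i < 20; ++i) b[i] = (id >> i) & 1;
    out[id] = oracle_categorize(b, 5, 4, min_run, max_stray);
  }
  return out;
}
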