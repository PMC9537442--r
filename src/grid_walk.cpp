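// Core grid routines: the stochastic movement step loop and Dijkstra
// shortest paths on the 8-connected pixel graph. Both use the shared
// cost convention: moving i -> j costs len(i,j) * (r_i + r_j) / 2 with
// len = 1 for cardinal and sqrt(2) for diagonal moves.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// fixed neighbour order; all tie-breaking follows this order
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const double SQRT2 = 1.4142135623730951;

static inline double stepLen(int k) {
  return (DR[k] != 0 && DC[k] != 0) ? SQRT2 : 1.0;
}

// One stochastic path. Coordinates are 0-based here; the R wrapper
// converts. destRow < 0 means no destination. Draws come from R's RNG
// so set.seed() at the R level controls reproducibility.
// [[Rcpp::export(name = ".cpp_walk_path")]]
List cpp_walk_path(NumericMatrix res, NumericMatrix risk,
                   int srow, int scol, int destRow, int destCol,
                   bool useEnergy, bool useAttraction, bool useRisk,
                   double C, double D, double E, double beta,
                   double riskMax, int maxSteps) {
  const int nr = res.nrow(), nc = res.ncol();
  if (nr * nc < 2) stop("degenerate grid: no admissible neighbours");
  std::vector<int> rows, cols;
  rows.reserve(maxSteps + 1); cols.reserve(maxSteps + 1);
  int r = srow, c = scol, prevDir = -1;
  double acc = 0.0;
  rows.push_back(r); cols.push_back(c);
  std::string reason = "step_cap";
  const double Cp = C * (1.0 - D);

  double w[8]; int nbr[8];
  for (int step = 0; step < maxSteps; ++step) {
    // admissible Moore neighbours in fixed order
    int na = 0;
    double wsum = 0.0;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      nbr[na] = k;
      w[na] = useAttraction ? 1.0 / res(rr, cc) : 1.0;
      wsum += w[na];
      ++na;
    }
    // mixture: (1 - C' - D) P_mech + C' P_persist + D P_dest, with the
    // persistence mass folded into P_mech when no continuation exists
    double contW = 0.0;
    int contIdx = -1;
    if (Cp > 0.0 && prevDir >= 0) {
      int rr = r + DR[prevDir], cc = c + DC[prevDir];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) {
        for (int a = 0; a < na; ++a) if (nbr[a] == prevDir) { contIdx = a; break; }
      }
    }
    int destIdx = -1;
    if (D > 0.0) {
      double best = R_PosInf;
      for (int a = 0; a < na; ++a) {
        double dr = (double)(r + DR[nbr[a]]) - destRow;
        double dc = (double)(c + DC[nbr[a]]) - destCol;
        double d2 = dr * dr + dc * dc;
        if (d2 < best) { best = d2; destIdx = a; }  // strict: first wins ties
      }
    }
    double mechMass = 1.0 - D - (contIdx >= 0 ? Cp : 0.0);
    double p[8], psum = 0.0;
    for (int a = 0; a < na; ++a) {
      p[a] = mechMass * w[a] / wsum;
      if (a == contIdx) p[a] += Cp;
      if (a == destIdx) p[a] += D;
      psum += p[a];
    }
    // draw the next neighbour
    double u = R::runif(0.0, 1.0) * psum;
    int pick = na - 1;
    double cum = 0.0;
    for (int a = 0; a < na; ++a) {
      cum += p[a];
      if (u <= cum) { pick = a; break; }
    }
    int k = nbr[pick];
    int rr = r + DR[k], cc = c + DC[k];
    double moveCost = stepLen(k) * (res(r, c) + res(rr, cc)) / 2.0;
    if (useEnergy && acc + moveCost >= E) { reason = "energy_exhausted"; break; }
    r = rr; c = cc;
    acc += moveCost;
    prevDir = k;
    rows.push_back(r); cols.push_back(c);
    if (D > 0.0 && r == destRow && c == destCol) { reason = "destination_reached"; break; }
    if (useRisk) {
      double pDeath = 1.0 - std::exp(-beta * risk(r, c) / riskMax);
      if (R::runif(0.0, 1.0) < pDeath) { reason = "mortality"; break; }
    }
    (void)contW;
  }
  int n = rows.size();
  IntegerMatrix coords(n, 2);
  for (int i = 0; i < n; ++i) { coords(i, 0) = rows[i]; coords(i, 1) = cols[i]; }
  return List::create(Named("coords") = coords, Named("reason") = reason);
}

// Aggregate many walks into a visit-count surface. Seeding is done per
// path at the R level; this just loops for speed when sources and
// destinations are fixed in advance.
// [[Rcpp::export(name = ".cpp_accumulate_path")]]
void cpp_accumulate_path(IntegerMatrix coords, NumericMatrix counts) {
  for (int i = 0; i < coords.nrow(); ++i)
    counts(coords(i, 0), coords(i, 1)) += 1.0;
}

// Dijkstra on the pixel graph. sources are 0-based node indices
// (idx = row * ncol + col). Returns minimum accumulated cost to the
// nearest source for every pixel, plus predecessors for path
// extraction (predecessor of a source is -1). Tie-breaking is
// deterministic: the heap pops equal distances in node-index order and
// relaxation only replaces a predecessor on strict improvement, with
// neighbours examined in the fixed order above.
// [[Rcpp::export(name = ".cpp_grid_dijkstra")]]
List cpp_grid_dijkstra(NumericMatrix res, IntegerVector sources) {
  const int nr = res.nrow(), nc = res.ncol(), N = nr * nc;
  std::vector<double> dist(N, R_PosInf);
  std::vector<int> pred(N, -1);
  std::vector<char> done(N, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i];
    if (s < 0 || s >= N) stop("source index out of bounds");
    dist[s] = 0.0;
    q.push(QE(0.0, s));
  }
  while (!q.empty()) {
    QE top = q.top(); q.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    int ur = u / nc, uc = u % nc;
    double ru = res(ur, uc);
    for (int k = 0; k < 8; ++k) {
      int vr = ur + DR[k], vc = uc + DC[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vr * nc + vc;
      if (done[v]) continue;
      double w = stepLen(k) * (ru + res(vr, vc)) / 2.0;
      if (dist[u] + w < dist[v]) {
        dist[v] = dist[u] + w;
        pred[v] = u;
        q.push(QE(dist[v], v));
      }
    }
  }
  NumericMatrix dmat(nr, nc);
  IntegerMatrix pmat(nr, nc);
  for (int i = 0; i < N; ++i) {
    dmat(i / nc, i % nc) = dist[i];
    pmat(i / nc, i % nc) = pred[i];
  }
  return List::create(Named("dist") = dmat, Named("pred") = pmat);
}
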