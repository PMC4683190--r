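// Streaming detector cores. All detectors are stateful objects held behind
// external pointers so that R drivers can feed chunks of arbitrary size and
// obtain chunk-size-independent, bit-reproducible event streams.
#include <Rcpp.h>
#include <deque>
#include <unordered_map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// per-frame median across channels
// [[Rcpp::export]]
NumericVector row_medians_cpp(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nr);
  if (nc == 0) stop("no channels");
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = x(i, j);
    int h = nc / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (nc % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
      m = 0.5 * (m + buf[h - 1]);
    }
    out[i] = m;
  }
  return out;
}

// ---------------------------------------------------------------------------
// incremental baseline/variability update (shared by all detectors)
//
// b tracks a lower-tercile quantile: up by 0.5*brate*v when x > b+v, down by
// brate*v when x < b-v. v shrinks when x in (b-v, b] or x <= b-6v, grows when
// x in (b-5v, b-v]. Conditions use the pre-update state; v is floored.
struct StateParams {
  double vstep;   // f_v/f_s, uV per frame
  double brate;   // f_b/(f_s v): down-step in units of v (up-step is half)
  double vfloor;
};

static inline void update_bv(double x, double &b, double &v,
                             const StateParams &p) {
  double b0 = b, v0 = v;
  if (x > b0 + v0) b += 0.5 * p.brate * v0;
  else if (x < b0 - v0) b -= p.brate * v0;
  if ((x > b0 - v0 && x <= b0) || x <= b0 - 6.0 * v0) v -= p.vstep;
  else if (x > b0 - 5.0 * v0 && x <= b0 - v0) v += p.vstep;
  if (v < p.vfloor) v = p.vfloor;
}

// [[Rcpp::export]]
List track_baseline_cpp(NumericVector x, double vstep, double brate,
                        double vfloor, double v0) {
  int n = x.size();
  NumericVector b(n), v(n);
  StateParams p{vstep, brate, vfloor};
  double bb = n > 0 ? x[0] : 0.0, vv = v0;
  for (int t = 0; t < n; ++t) {
    update_bv(x[t], bb, vv, p);
    b[t] = bb; v[t] = vv;
  }
  return List::create(_["b"] = b, _["v"] = v);
}

// ---------------------------------------------------------------------------
// Online (single-channel) detector
// robust per-channel start values: median for b, scaled MAD for v. The
// variability update is bistable (a v far below the noise spread keeps
// shrinking through the spike-compensation branch), so v must start at or
// above the noise scale; from above it converges down to its equilibrium.
static void robust_init(const std::vector<double> &buf, int n, double vfloor,
                        double &b, double &v) {
  std::vector<double> tmp(buf.begin(), buf.begin() + n);
  std::nth_element(tmp.begin(), tmp.begin() + n / 2, tmp.end());
  double med = tmp[n / 2];
  for (int i = 0; i < n; ++i) tmp[i] = std::abs(buf[i] - med);
  std::nth_element(tmp.begin(), tmp.begin() + n / 2, tmp.end());
  b = med;
  v = std::max(1.4826 * tmp[n / 2], vfloor);
}

struct OnlineDet {
  int nch;
  double fs, theta, theta_b, theta_ev;
  int tau_ev, tau_event, burn, ring;
  int initf;                     // frames buffered for robust b/v start
  std::vector<double> initbuf;
  StateParams sp;
  double v0;
  bool subtract_median, initialized;
  long t;  // 0-based global frame counter
  std::vector<double> b, v;
  std::vector<double> dev;       // ring of (b - x)/v, nch * ring
  std::vector<char> below;
  std::vector<long> t_cross, t_peak;
  std::vector<double> peak;
  std::vector<char> has_pend, pend_repol;
  std::vector<long> pend_frame, pend_cross, pend_deadline;
  std::vector<double> pend_amp;
  // output accumulators
  std::vector<double> ev_frame, ev_ch, ev_amp, ev_repol;

  OnlineDet(int nch_, double fs_, double theta_, double theta_b_,
            double theta_ev_, int tau_ev_, int tau_event_, double vstep,
            double brate, double vfloor, double v0_, int burn_,
            bool submed, int initf_)
      : nch(nch_), fs(fs_), theta(theta_), theta_b(theta_b_),
        theta_ev(theta_ev_), tau_ev(tau_ev_), tau_event(tau_event_),
        burn(burn_), ring(64), initf(initf_),
        initbuf((size_t)nch_ * (initf_ > 0 ? initf_ : 0)),
        sp{vstep, brate, vfloor}, v0(v0_),
        subtract_median(submed), initialized(false), t(0),
        b(nch_), v(nch_, v0_), dev(nch_ * 64, 0.0), below(nch_, 0),
        t_cross(nch_, 0), t_peak(nch_, 0), peak(nch_, 0.0),
        has_pend(nch_, 0), pend_repol(nch_, 0), pend_frame(nch_, 0),
        pend_cross(nch_, 0), pend_deadline(nch_, 0), pend_amp(nch_, 0.0) {}

  double area(int c, long cross, long pk) {
    long lo = std::max(cross, pk + tau_ev - (long)ring + 1);
    long hi = pk + tau_ev;
    double s = 0.0;
    for (long u = lo; u <= hi; ++u) s += dev[(size_t)c * ring + (u % ring)];
    return s;
  }

  void emit(int c) {
    if (pend_frame[c] >= burn && area(c, pend_cross[c], pend_frame[c]) > theta_ev) {
      ev_frame.push_back((double)(pend_frame[c] + 1));  // 1-based
      ev_ch.push_back((double)(c + 1));
      ev_amp.push_back(pend_amp[c]);
      ev_repol.push_back(pend_repol[c] ? 1.0 : 0.0);
    }
    has_pend[c] = 0;
  }

  void candidate(int c, long pk, double amp, long cross) {
    if (has_pend[c]) {
      if (pk <= pend_deadline[c]) {
        if (amp > pend_amp[c]) {  // deeper minimum voids the earlier event
          pend_frame[c] = pk; pend_amp[c] = amp; pend_cross[c] = cross;
          pend_deadline[c] = pk + tau_event; pend_repol[c] = 0;
        }
        return;  // shallower follower within tau_event: refractory resolves it
      }
      emit(c);
    }
    has_pend[c] = 1;
    pend_frame[c] = pk; pend_amp[c] = amp; pend_cross[c] = cross;
    pend_deadline[c] = pk + tau_event; pend_repol[c] = 0;
  }

  void feed(NumericMatrix x) {
    int nf = x.nrow();
    if (x.ncol() != nch) stop("chunk channel count mismatch");
    std::vector<double> medbuf(nch);
    for (int f = 0; f < nf; ++f) {
      double g = 0.0;
      if (subtract_median && nch > 1) {
        for (int c = 0; c < nch; ++c) medbuf[c] = x(f, c);
        int h = nch / 2;
        std::nth_element(medbuf.begin(), medbuf.begin() + h, medbuf.end());
        g = medbuf[h];
        if (nch % 2 == 0) {
          std::nth_element(medbuf.begin(), medbuf.begin() + h - 1,
                           medbuf.begin() + h);
          g = 0.5 * (g + medbuf[h - 1]);
        }
      }
      if (t < initf) {
        for (int c = 0; c < nch; ++c)
          initbuf[(size_t)c * initf + t] = x(f, c) - g;
        if (t == initf - 1)
          for (int c = 0; c < nch; ++c)
            robust_init(std::vector<double>(initbuf.begin() + (size_t)c * initf,
                                            initbuf.begin() + (size_t)(c + 1) * initf),
                        initf, sp.vfloor, b[c], v[c]);
        initialized = true;
        ++t;
        continue;
      }
      for (int c = 0; c < nch; ++c) {
        double xc = x(f, c) - g;
        if (!initialized) b[c] = xc;
        update_bv(xc, b[c], v[c], sp);
        double d = (b[c] - xc) / v[c];
        dev[(size_t)c * ring + (t % ring)] = d;
        if (!below[c]) {
          if (d > theta) { below[c] = 1; t_cross[c] = t; t_peak[c] = t; peak[c] = d; }
        } else {
          if (d > peak[c]) { peak[c] = d; t_peak[c] = t; }
          if (d <= theta) {
            below[c] = 0;
            candidate(c, t_peak[c], peak[c], t_cross[c]);
          }
        }
        if (has_pend[c]) {
          if (t > pend_deadline[c]) {
            // an ongoing deeper episode whose peak fell inside the pending
            // window voids the pending event (no-larger-minimum criterion)
            if (below[c] && t_peak[c] <= pend_deadline[c] &&
                peak[c] > pend_amp[c])
              has_pend[c] = 0;
            else
              emit(c);
          } else if (d < -theta_b) {
            pend_repol[c] = 1;  // x > b + theta_b * v: repolarization seen
          }
        }
      }
      initialized = true;
      ++t;
    }
  }

  void flush() {
    for (int c = 0; c < nch; ++c) {
      if (below[c]) { below[c] = 0; candidate(c, t_peak[c], peak[c], t_cross[c]); }
      if (has_pend[c]) emit(c);
    }
  }

  DataFrame take() {
    DataFrame out = DataFrame::create(
        _["frame"] = NumericVector(ev_frame.begin(), ev_frame.end()),
        _["channel"] = NumericVector(ev_ch.begin(), ev_ch.end()),
        _["amplitude"] = NumericVector(ev_amp.begin(), ev_amp.end()),
        _["repolarizing"] = NumericVector(ev_repol.begin(), ev_repol.end()));
    ev_frame.clear(); ev_ch.clear(); ev_amp.clear(); ev_repol.clear();
    return out;
  }
};

// [[Rcpp::export]]
SEXP online_new(int nch, double fs, double theta, double theta_b,
                double theta_ev, int tau_ev, int tau_event, double vstep,
                double brate, double vfloor, double v0, int burn,
                bool subtract_median, int init_frames) {
  XPtr<OnlineDet> p(new OnlineDet(nch, fs, theta, theta_b, theta_ev, tau_ev,
                                  tau_event, vstep, brate, vfloor, v0, burn,
                                  subtract_median, init_frames), true);
  return p;
}

// [[Rcpp::export]]
void online_feed(SEXP ptr, NumericMatrix x) { XPtr<OnlineDet>(ptr)->feed(x); }

// [[Rcpp::export]]
void online_flush(SEXP ptr) { XPtr<OnlineDet>(ptr)->flush(); }

// [[Rcpp::export]]
DataFrame online_take(SEXP ptr) { return XPtr<OnlineDet>(ptr)->take(); }

// [[Rcpp::export]]
List online_state(SEXP ptr) {
  XPtr<OnlineDet> p(ptr);
  return List::create(_["b"] = NumericVector(p->b.begin(), p->b.end()),
                      _["v"] = NumericVector(p->v.begin(), p->v.end()));
}

// ---------------------------------------------------------------------------
// Interpolating detector on real + virtual channel grids
struct InterpDet {
  int nr, nc, nch, nvr, nvc, nv, L;
  double fs, theta, theta_b, wcs;
  int tau_event, tau_coinc, burn, tau_pre, tau_post;
  int initf; std::vector<double> initbuf;
  StateParams sp; double v0;
  bool cutouts, initialized;
  long t;                       // frames consumed (0-based); n/m lag one frame
  double g_prev; bool has_g;
  std::vector<double> b, v, h, c_prev;
  std::vector<double> sum_v, sum_h; long n_avg;
  int RD, RB;
  std::vector<double> nring, mring;     // L x RD (normalized, min-over-2)
  std::vector<double> q0, q1, q2;       // interpolated fields, last 3 frames
  std::vector<double> vI;               // interpolated variability (current)
  std::vector<double> xring;            // nch x RB median-subtracted raw
  std::vector<double> gring;            // RB global medians
  std::vector<std::vector<int>> nbr;    // 8-neighbour location ids
  struct Acc {
    long frame; int loc; double amp; bool repol;
    std::vector<double> bsnap, vbar, hbar;  // per cutout slot
    std::vector<int> chan;                  // 0 = unavailable slot
    std::vector<char> det;                  // detection-channel mask
    int center_slot;
  };
  std::deque<Acc> queue;
  // outputs
  std::vector<double> ev_frame, ev_loc, ev_amp, ev_repol;
  std::vector<double> cut_snip, cut_g, cut_b, cut_vbar, cut_hbar;
  std::vector<int> cut_chan, cut_det, cut_center;
  int SLOTS, T;

  int vloc(int vr, int vc) const { return nch + vr * nvc + vc; }
  bool isv(int l) const { return l >= nch; }

  InterpDet(int nr_, int nc_, double fs_, double theta_, double theta_b_,
            double wcs_, int tau_event_, int tau_coinc_, double vstep,
            double brate, double vfloor, double v0_, int burn_, int tau_pre_,
            int tau_post_, bool cutouts_, int initf_)
      : nr(nr_), nc(nc_), nch(nr_ * nc_), nvr(nr_ - 1), nvc(nc_ - 1),
        nv((nr_ - 1) * (nc_ - 1)), L(nch + nv), fs(fs_), theta(theta_),
        theta_b(theta_b_), wcs(wcs_), tau_event(tau_event_),
        tau_coinc(tau_coinc_), burn(burn_), tau_pre(tau_pre_),
        tau_post(tau_post_), initf(initf_),
        initbuf((size_t)(nr_ * nc_) * (initf_ > 0 ? initf_ : 0)),
        sp{vstep, brate, vfloor}, v0(v0_),
        cutouts(cutouts_), initialized(false), t(0), g_prev(0.0), has_g(false),
        b(nch), v(nch, v0_), h(nch, 0.0), c_prev(nch, 0.0),
        sum_v(nch, 0.0), sum_h(nch, 0.0), n_avg(0),
        RD(16), RB(40), nring((size_t)L * 16, 0.0), mring((size_t)L * 16, 0.0),
        q0(L, 0.0), q1(L, 0.0), q2(L, 0.0), vI(L, v0_),
        xring((size_t)(nr_ * nc_) * 40, 0.0), gring(40, 0.0), nbr(L) {
    if (tau_event + tau_coinc + 3 > RD) stop("tau_event + tau_coinc too large");
    if (tau_pre + tau_post + 3 > RB) stop("tau_pre + tau_post too large");
    if (nr < 2 || nc < 2) stop("interpolating detection needs a >= 2x2 grid");
    SLOTS = 12; T = tau_pre + tau_post + 1;
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        int l = r * nc + c;
        if (r > 0) nbr[l].push_back((r - 1) * nc + c);
        if (r < nr - 1) nbr[l].push_back((r + 1) * nc + c);
        if (c > 0) nbr[l].push_back(r * nc + c - 1);
        if (c < nc - 1) nbr[l].push_back(r * nc + c + 1);
        for (int dr = -1; dr <= 0; ++dr)
          for (int dc = -1; dc <= 0; ++dc) {
            int vr = r + dr, vc = c + dc;
            if (vr >= 0 && vr < nvr && vc >= 0 && vc < nvc)
              nbr[l].push_back(vloc(vr, vc));
          }
      }
    for (int vr = 0; vr < nvr; ++vr)
      for (int vc = 0; vc < nvc; ++vc) {
        int l = vloc(vr, vc);
        nbr[l].push_back(vr * nc + vc); nbr[l].push_back(vr * nc + vc + 1);
        nbr[l].push_back((vr + 1) * nc + vc); nbr[l].push_back((vr + 1) * nc + vc + 1);
        if (vr > 0) nbr[l].push_back(vloc(vr - 1, vc));
        if (vr < nvr - 1) nbr[l].push_back(vloc(vr + 1, vc));
        if (vc > 0) nbr[l].push_back(vloc(vr, vc - 1));
        if (vc < nvc - 1) nbr[l].push_back(vloc(vr, vc + 1));
      }
  }

  // location l wins a tie against neighbour m when it is on the real grid and
  // m is virtual, or (same grid) it has the lower index
  bool tie_wins(int l, int m) const {
    if (isv(l) != isv(m)) return !isv(l);
    return l < m;
  }

  double &NR(int l, long u) { return nring[(size_t)l * RD + (u % RD)]; }
  double &MR(int l, long u) { return mring[(size_t)l * RD + (u % RD)]; }
  double &XR(int c, long u) { return xring[(size_t)c * RB + (u % RB)]; }

  void pop_ready(long now) {
    while (!queue.empty() && now >= queue.front().frame + tau_post) {
      Acc &a = queue.front();
      ev_frame.push_back((double)(a.frame + 1));
      ev_loc.push_back((double)(a.loc + 1));
      ev_amp.push_back(a.amp);
      ev_repol.push_back(a.repol ? 1.0 : 0.0);
      if (cutouts) {
        cut_center.push_back(a.center_slot);
        for (int s = 0; s < SLOTS; ++s) {
          cut_chan.push_back(a.chan[s]);
          cut_det.push_back(a.det[s]);
          cut_b.push_back(a.bsnap[s]);
          cut_vbar.push_back(a.vbar[s]);
          cut_hbar.push_back(a.hbar[s]);
          for (int k = 0; k < T; ++k) {
            long u = a.frame - tau_pre + k;
            cut_snip.push_back((a.chan[s] > 0 && u >= 0 && u <= t - 1)
                                   ? XR(a.chan[s] - 1, u) : 0.0);
          }
        }
        for (int k = 0; k < T + 1; ++k) {
          long u = a.frame - tau_pre - 1 + k;
          cut_g.push_back((u >= 0 && u <= t - 1) ? gring[u % RB] : 0.0);
        }
      }
      queue.pop_front();
    }
  }

  void accept(long tau, int l, double amp, bool repol) {
    Acc a; a.frame = tau; a.loc = l; a.amp = amp; a.repol = repol;
    a.center_slot = -1;
    a.chan.assign(SLOTS, 0); a.det.assign(SLOTS, 0);
    a.bsnap.assign(SLOTS, 0.0); a.vbar.assign(SLOTS, 0.0); a.hbar.assign(SLOTS, 0.0);
    if (cutouts) {
      double vb, hb;
      int s = 0;
      if (!isv(l)) {
        int r = l / nc, c = l % nc;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc, ++s) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            int ch = rr * nc + cc;
            a.chan[s] = ch + 1;
            if ((dr == 0 && dc == 0)) a.center_slot = s;
            if (std::abs(dr) + std::abs(dc) <= 1) a.det[s] = 1;
            a.bsnap[s] = b[ch];
            vb = n_avg > 0 ? sum_v[ch] / n_avg : v[ch];
            hb = n_avg > 0 ? sum_h[ch] / n_avg : h[ch];
            a.vbar[s] = vb; a.hbar[s] = hb;
          }
      } else {
        int vi = l - nch, vr = vi / nvc, vc = vi % nvc;
        for (int rr = vr - 1; rr <= vr + 2; ++rr)
          for (int cc = vc - 1; cc <= vc + 1; ++cc, ++s) {
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            int ch = rr * nc + cc;
            a.chan[s] = ch + 1;
            if ((rr == vr || rr == vr + 1) && (cc == vc || cc == vc + 1))
              a.det[s] = 1;
            a.bsnap[s] = b[ch];
            vb = n_avg > 0 ? sum_v[ch] / n_avg : v[ch];
            hb = n_avg > 0 ? sum_h[ch] / n_avg : h[ch];
            a.vbar[s] = vb; a.hbar[s] = hb;
          }
      }
    }
    queue.push_back(a);
  }

  void feed(NumericMatrix x) {
    int nf = x.nrow();
    if (x.ncol() != nch) stop("chunk channel count mismatch");
    std::vector<double> medbuf(nch), y(nch);
    for (int f = 0; f < nf; ++f) {
      // global median and per-channel correction
      for (int c = 0; c < nch; ++c) medbuf[c] = x(f, c);
      int hn = nch / 2;
      std::nth_element(medbuf.begin(), medbuf.begin() + hn, medbuf.end());
      double g = medbuf[hn];
      if (nch % 2 == 0) {
        std::nth_element(medbuf.begin(), medbuf.begin() + hn - 1,
                         medbuf.begin() + hn);
        g = 0.5 * (g + medbuf[hn - 1]);
      }
      double dg = has_g ? g - g_prev : 0.0;
      gring[t % RB] = g;
      for (int c = 0; c < nch; ++c) {
        double xs = x(f, c) - g;
        XR(c, t) = xs;
        double ci = xs - h[c] * dg;
        double dci = ci - c_prev[c];
        if (dg != 0.0 && dci != 0.0)
          h[c] += ((dci > 0) == (dg > 0)) ? 1.0 / fs : -1.0 / fs;
        c_prev[c] = ci;
        if (!initialized) b[c] = ci;
        if (t < initf) initbuf[(size_t)c * initf + t] = ci;
        update_bv(ci, b[c], v[c], sp);
        y[c] = ci - b[c];
        if (t >= burn) { sum_v[c] += v[c]; sum_h[c] += h[c]; }
      }
      if (initf > 0 && t == initf - 1)
        for (int c = 0; c < nch; ++c) {
          robust_init(std::vector<double>(initbuf.begin() + (size_t)c * initf,
                                          initbuf.begin() + (size_t)(c + 1) * initf),
                      initf, sp.vfloor, b[c], v[c]);
          y[c] = c_prev[c] - b[c];
        }
      if (t >= burn) ++n_avg;
      initialized = true;
      g_prev = g; has_g = true;
      // rotate interpolation rings
      std::swap(q0, q1); std::swap(q1, q2);
      // five-channel field on the real grid
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c) {
          int l = r * nc + c;
          int ids[4]; int np = 0;
          if (r > 0) ids[np++] = (r - 1) * nc + c;
          if (r < nr - 1) ids[np++] = (r + 1) * nc + c;
          if (c > 0) ids[np++] = l - 1;
          if (c < nc - 1) ids[np++] = l + 1;
          int drop = -1;
          if (np == 4) {
            double amin = std::abs(y[ids[0]]); drop = 0;
            for (int k = 1; k < 4; ++k) {
              double ak = std::abs(y[ids[k]]);
              if (ak < amin) { amin = ak; drop = k; }
            }
          }
          double qs = wcs * y[l], vs = wcs * v[l], wsum = wcs;
          for (int k = 0; k < np; ++k) {
            if (k == drop) continue;
            qs += y[ids[k]]; vs += v[ids[k]]; wsum += 1.0;
          }
          q2[l] = qs / wsum; vI[l] = vs / wsum;
        }
      // four-channel field on the virtual grid
      for (int vr = 0; vr < nvr; ++vr)
        for (int vc = 0; vc < nvc; ++vc) {
          int l = vloc(vr, vc);
          int c00 = vr * nc + vc;
          int ids[4] = {c00, c00 + 1, c00 + nc, c00 + nc + 1};
          int drop = 0; double amin = std::abs(y[ids[0]]);
          for (int k = 1; k < 4; ++k) {
            double ak = std::abs(y[ids[k]]);
            if (ak < amin) { amin = ak; drop = k; }
          }
          double qs = 0.0, vs = 0.0;
          for (int k = 0; k < 4; ++k) {
            if (k == drop) continue;
            qs += y[ids[k]]; vs += v[ids[k]];
          }
          q2[l] = qs / 3.0; vI[l] = vs / 3.0;
        }
      // smoothed, normalized field for frame t-1 and its two-frame minimum
      if (t >= 2) {
        long u = t - 1;
        for (int l = 0; l < L; ++l) {
          double nn = (q0[l] + q1[l] + q2[l]) / (3.0 * vI[l]);
          NR(l, u) = nn;
          MR(l, u) = (u >= 1) ? std::min(nn, NR(l, u - 1)) : nn;
        }
        // decide candidates at tau = u - tau_event
        long tau = u - tau_event;
        if (tau >= burn && tau - tau_coinc >= 1) {
          for (int l = 0; l < L; ++l) {
            double m0 = MR(l, tau);
            if (m0 >= -theta) continue;
            if (MR(l, tau - 1) < m0) continue;
            bool ok = true;
            for (long w = tau + 1; w <= tau + tau_event && ok; ++w)
              if (MR(l, w) <= m0) ok = false;
            if (!ok) continue;
            bool repol = false;
            for (long w = tau + 1; w <= tau + tau_event; ++w)
              if (NR(l, w) > theta_b) { repol = true; break; }
            for (size_t k = 0; k < nbr[l].size() && ok; ++k) {
              int m = nbr[l][k];
              for (long w = tau - tau_coinc; w <= tau + tau_coinc && ok; ++w) {
                double mv = MR(m, w);
                if (mv < m0 || (mv == m0 && !tie_wins(l, m))) ok = false;
              }
            }
            if (ok) accept(tau, l, -m0, repol);
          }
        }
        pop_ready(u);
      }
      ++t;
    }
  }

  void flush() { pop_ready(t + tau_post + 1); }

  List take() {
    List ev = List::create(
        _["frame"] = NumericVector(ev_frame.begin(), ev_frame.end()),
        _["loc"] = NumericVector(ev_loc.begin(), ev_loc.end()),
        _["amplitude"] = NumericVector(ev_amp.begin(), ev_amp.end()),
        _["repolarizing"] = NumericVector(ev_repol.begin(), ev_repol.end()));
    List out;
    if (cutouts) {
      out = List::create(
          _["events"] = ev,
          _["snip"] = NumericVector(cut_snip.begin(), cut_snip.end()),
          _["g"] = NumericVector(cut_g.begin(), cut_g.end()),
          _["b"] = NumericVector(cut_b.begin(), cut_b.end()),
          _["vbar"] = NumericVector(cut_vbar.begin(), cut_vbar.end()),
          _["hbar"] = NumericVector(cut_hbar.begin(), cut_hbar.end()),
          _["chan"] = IntegerVector(cut_chan.begin(), cut_chan.end()),
          _["det"] = IntegerVector(cut_det.begin(), cut_det.end()),
          _["center_slot"] = IntegerVector(cut_center.begin(), cut_center.end()),
          _["slots"] = SLOTS, _["snip_len"] = T);
    } else {
      out = List::create(_["events"] = ev);
    }
    ev_frame.clear(); ev_loc.clear(); ev_amp.clear(); ev_repol.clear();
    cut_snip.clear(); cut_g.clear(); cut_b.clear(); cut_vbar.clear();
    cut_hbar.clear(); cut_chan.clear(); cut_det.clear(); cut_center.clear();
    return out;
  }
};

// [[Rcpp::export]]
SEXP interp_new(int nr, int nc, double fs, double theta, double theta_b,
                double wcs, int tau_event, int tau_coinc, double vstep,
                double brate, double vfloor, double v0, int burn, int tau_pre,
                int tau_post, bool cutouts, int init_frames) {
  XPtr<InterpDet> p(new InterpDet(nr, nc, fs, theta, theta_b, wcs, tau_event,
                                  tau_coinc, vstep, brate, vfloor, v0, burn,
                                  tau_pre, tau_post, cutouts, init_frames), true);
  return p;
}

// [[Rcpp::export]]
void interp_feed(SEXP ptr, NumericMatrix x) { XPtr<InterpDet>(ptr)->feed(x); }

// [[Rcpp::export]]
void interp_flush(SEXP ptr) { XPtr<InterpDet>(ptr)->flush(); }

// [[Rcpp::export]]
List interp_take(SEXP ptr) { return XPtr<InterpDet>(ptr)->take(); }

// [[Rcpp::export]]
List interp_state(SEXP ptr) {
  XPtr<InterpDet> p(ptr);
  int n = p->nch;
  NumericVector vbar(n), hbar(n);
  for (int c = 0; c < n; ++c) {
    vbar[c] = p->n_avg > 0 ? p->sum_v[c] / p->n_avg : p->v[c];
    hbar[c] = p->n_avg > 0 ? p->sum_h[c] / p->n_avg : p->h[c];
  }
  return List::create(_["b"] = NumericVector(p->b.begin(), p->b.end()),
                      _["v"] = NumericVector(p->v.begin(), p->v.end()),
                      _["h"] = NumericVector(p->h.begin(), p->h.end()),
                      _["vbar"] = vbar, _["hbar"] = hbar);
}

// ---------------------------------------------------------------------------
// Conventional band-pass + threshold detector (streaming IIR per channel)
struct ThreshDet {
  int nch, ord;
  std::vector<double> bc, ac;        // filter coefficients, a[0] == 1
  std::vector<double> z;             // nch x ord DF2T states
  std::vector<double> sd;
  double theta;
  long t; int burn;
  std::vector<double> y1, y2;        // last two outputs per channel
  std::vector<double> ev_frame, ev_ch, ev_amp;

  ThreshDet(int nch_, NumericVector b_, NumericVector a_, NumericVector sd_,
            double theta_, int burn_)
      : nch(nch_), ord(b_.size() - 1), bc(b_.begin(), b_.end()),
        ac(a_.begin(), a_.end()), z((size_t)nch_ * (b_.size() - 1), 0.0),
        sd(sd_.begin(), sd_.end()), theta(theta_), t(0), burn(burn_),
        y1(nch_, 0.0), y2(nch_, 0.0) {}

  void feed(NumericMatrix x) {
    int nf = x.nrow();
    for (int f = 0; f < nf; ++f) {
      for (int c = 0; c < nch; ++c) {
        double *zc = &z[(size_t)c * ord];
        double xi = x(f, c);
        double yo = bc[0] * xi + zc[0];
        for (int k = 0; k < ord - 1; ++k)
          zc[k] = bc[k + 1] * xi - ac[k + 1] * yo + zc[k + 1];
        zc[ord - 1] = bc[ord] * xi - ac[ord] * yo;
        // local minimum below -theta*sd at frame t-1
        if (t >= burn + 2 && y1[c] < -theta * sd[c] && y1[c] <= y2[c] &&
            y1[c] < yo) {
          ev_frame.push_back((double)t);  // t-1 in 0-based == t in 1-based
          ev_ch.push_back((double)(c + 1));
          ev_amp.push_back(-y1[c] / sd[c]);
        }
        y2[c] = y1[c]; y1[c] = yo;
      }
      ++t;
    }
  }

  DataFrame take() {
    DataFrame out = DataFrame::create(
        _["frame"] = NumericVector(ev_frame.begin(), ev_frame.end()),
        _["channel"] = NumericVector(ev_ch.begin(), ev_ch.end()),
        _["amplitude"] = NumericVector(ev_amp.begin(), ev_amp.end()));
    ev_frame.clear(); ev_ch.clear(); ev_amp.clear();
    return out;
  }
};

// [[Rcpp::export]]
SEXP thresh_new(int nch, NumericVector b, NumericVector a, NumericVector sd,
                double theta, int burn) {
  XPtr<ThreshDet> p(new ThreshDet(nch, b, a, sd, theta, burn), true);
  return p;
}

// [[Rcpp::export]]
void thresh_feed(SEXP ptr, NumericMatrix x) { XPtr<ThreshDet>(ptr)->feed(x); }

// [[Rcpp::export]]
DataFrame thresh_take(SEXP ptr) { return XPtr<ThreshDet>(ptr)->take(); }

// ---------------------------------------------------------------------------
// Greedy spatio-temporal duplicate suppression.
// Events are visited in descending amplitude (ties: earlier frame, lower id);
// an event is kept iff no already-kept event lies within the spatio-temporal
// lockout. Returns a logical keep mask.
// [[Rcpp::export]]
LogicalVector dedup_cpp(NumericVector frame, NumericVector x, NumericVector y,
                        NumericVector amp, NumericVector id,
                        double radius_um, double window_frames) {
  int n = frame.size();
  LogicalVector keep(n, false);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int i, int j) {
    if (amp[i] != amp[j]) return amp[i] > amp[j];
    if (frame[i] != frame[j]) return frame[i] < frame[j];
    return id[i] < id[j];
  });
  double cell = radius_um > 0 ? radius_um : 1.0;
  std::unordered_map<long long, std::vector<int>> gridmap;
  auto key = [&](double xx, double yy) {
    long long cx = (long long)std::floor(xx / cell) + 1000000;
    long long cy = (long long)std::floor(yy / cell) + 1000000;
    return cx * 4000003LL + cy;
  };
  double r2 = radius_um * radius_um;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    bool ok = true;
    long long cx = (long long)std::floor(x[i] / cell);
    long long cy = (long long)std::floor(y[i] / cell);
    for (long long dx = -1; dx <= 1 && ok; ++dx)
      for (long long dy = -1; dy <= 1 && ok; ++dy) {
        auto it = gridmap.find((cx + dx + 1000000) * 4000003LL + (cy + dy + 1000000));
        if (it == gridmap.end()) continue;
        for (int j : it->second) {
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (std::abs(frame[i] - frame[j]) <= window_frames &&
              ddx * ddx + ddy * ddy <= r2) { ok = false; break; }
        }
      }
    if (ok) { keep[i] = true; gridmap[key(x[i], y[i])].push_back(i); }
  }
  return keep;
}

// ---------------------------------------------------------------------------
// column-wise order statistics matching stats::median / stats::quantile type 7
// [[Rcpp::export]]
NumericVector col_medians_cpp(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
    int h = nr / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (nr % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
      m = 0.5 * (buf[h - 1] + m);
    }
    out[j] = m;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col_quantile_cpp(NumericMatrix x, double p) {
  int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  double hh = (nr - 1) * p;
  int lo = (int)std::floor(hh);
  double g = hh - lo;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
    std::sort(buf.begin(), buf.end());
    out[j] = buf[lo] + g * (buf[lo + (lo + 1 < nr ? 1 : 0)] - buf[lo]);
  }
  return out;
}

// recursive AR(1) pass over columns: out[t] = phi*out[t-1] + eps[t]
// [[Rcpp::export]]
NumericMatrix ar1_cpp(NumericMatrix eps, NumericVector init, double phi) {
  int nr = eps.nrow(), nc = eps.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double prev = init[j];
    for (int i = 0; i < nr; ++i) {
      prev = phi * prev + eps(i, j);
      out(i, j) = prev;
    }
  }
  return out;
}
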