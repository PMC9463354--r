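#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Natural cubic spline through (x, y), x strictly increasing.
// Evaluated at xout; points left of x[0] get fill_left, right of x[n-1] fill_right.
static void natural_spline(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const double* xout, double* yout, int nout,
                           double fill_left, double fill_right) {
    const int n = (int) x.size();
    if (n < 2) stop("spline needs at least 2 knots");
    // second derivatives via tridiagonal solve (natural BCs)
    std::vector<double> m(n, 0.0), u(n, 0.0), z(n, 0.0);
    std::vector<double> h(n - 1);
    for (int i = 0; i < n - 1; ++i) h[i] = x[i + 1] - x[i];
    std::vector<double> l(n, 1.0);
    for (int i = 1; i < n - 1; ++i) {
        double alpha = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
        l[i] = 2.0 * (x[i + 1] - x[i - 1]) - h[i - 1] * u[i - 1];
        u[i] = h[i] / l[i];
        z[i] = (alpha - h[i - 1] * z[i - 1]) / l[i];
    }
    for (int i = n - 2; i >= 1; --i) m[i] = z[i] - u[i] * m[i + 1];
    for (int k = 0; k < nout; ++k) {
        double t = xout[k];
        if (t < x[0]) { yout[k] = fill_left; continue; }
        if (t > x[n - 1]) { yout[k] = fill_right; continue; }
        int j = (int) (std::upper_bound(x.begin(), x.end(), t) - x.begin()) - 1;
        if (j >= n - 1) j = n - 2;
        double dx = x[j + 1] - x[j];
        double a = (x[j + 1] - t) / dx, b = (t - x[j]) / dx;
        yout[k] = a * y[j] + b * y[j + 1] +
            ((a * a * a - a) * m[j] + (b * b * b - b) * m[j + 1]) * (dx * dx) / 6.0;
    }
}

// Causal discrete convolution, rectangle rule (x dt), truncated to length of f.
// [[Rcpp::export]]
NumericVector cpp_conv(NumericVector f, NumericVector g, double dt) {
    const int nf = f.size(), ng = g.size();
    NumericVector out(nf);
    for (int k = 0; k < nf; ++k) {
        double acc = 0.0;
        int jmax = std::min(k, ng - 1);
        for (int j = 0; j <= jmax; ++j) acc += f[k - j] * g[j];
        out[k] = acc * dt;
    }
    return out;
}

// Sample a cubic Bezier residue function (anchors P0=(0,1), P3=(p3x,0)) on the
// grid t = 0, dt, ..., (n-1)*dt. Dense parametric evaluation at <= 10 ms x-spacing,
// non-monotone x repaired by a running maximum (violation reported), then natural
// cubic spline resampling. R(0)=1 exactly, R(t > p3x) = 0.
// ctrl = [p1x, p1y, p2x, p2y, p3x]
// [[Rcpp::export]]
List cpp_bezier_residue(NumericVector ctrl, double dt, int n) {
    const double p1x = ctrl[0], p1y = ctrl[1], p2x = ctrl[2], p2y = ctrl[3],
                 p3x = ctrl[4];
    if (!(p3x > 0)) stop("p3x must be positive");
    int ntau = (int) std::ceil(p3x / 0.01) + 1;
    if (ntau < 51) ntau = 51;
    if (ntau > 20001) ntau = 20001;
    std::vector<double> xs(ntau), ys(ntau);
    double mono_pen = 0.0;
    for (int i = 0; i < ntau; ++i) {
        double tau = (double) i / (double) (ntau - 1);
        double c = 1.0 - tau;
        double b0 = c * c * c, b1 = 3.0 * c * c * tau, b2 = 3.0 * c * tau * tau,
               b3 = tau * tau * tau;
        xs[i] = b1 * p1x + b2 * p2x + b3 * p3x;       // P0x = 0
        ys[i] = b0 * 1.0 + b1 * p1y + b2 * p2y;        // P3y = 0
    }
    // repair x to strictly increasing, accumulating the violation magnitude
    for (int i = 1; i < ntau; ++i) {
        double dx = xs[i] - xs[i - 1];
        if (dx < 0) mono_pen += dx * dx;
        double floor_x = xs[i - 1] + 1e-9;
        if (xs[i] < floor_x) xs[i] = floor_x;
    }
    NumericVector vals(n);
    std::vector<double> tg(n);
    for (int k = 0; k < n; ++k) tg[k] = k * dt;
    natural_spline(xs, ys, tg.data(), REAL(vals), n, 1.0, 0.0);
    for (int k = 0; k < n; ++k) if (tg[k] > p3x) vals[k] = 0.0;
    vals[0] = 1.0;
    return List::create(_["values"] = vals, _["x_violation"] = mono_pen);
}

// Shift curve values by delta seconds (positive = later arrival), natural cubic
// spline interpolation at t - delta, zero fill before the record (pre-bolus) and
// after it.
// [[Rcpp::export]]
NumericVector cpp_shift_curve(NumericVector values, double dt, double delta) {
    const int n = values.size();
    std::vector<double> x(n), y(n), tq(n);
    for (int i = 0; i < n; ++i) { x[i] = i * dt; y[i] = values[i]; tq[i] = i * dt - delta; }
    NumericVector out(n);
    natural_spline(x, y, tq.data(), REAL(out), n, 0.0, 0.0);
    return out;
}

// Gamma vascular transport function on t = 0..(n-1)*dt, renormalized to unit
// discrete area (sum * dt = 1).
// [[Rcpp::export]]
NumericVector cpp_gamma_vtf(double s, double p, double dt, int n) {
    if (!(s > 0)) stop("s must be positive");
    if (p < 0) stop("p must be non-negative");
    NumericVector out(n);
    const double sp = s * p;
    const double lconst = (1.0 + sp) * std::log(s) - std::lgamma(1.0 + sp);
    double area = 0.0;
    for (int k = 0; k < n; ++k) {
        double t = k * dt;
        double v;
        if (t <= 0.0) v = (sp == 0.0) ? std::exp(lconst) : 0.0;
        else v = std::exp(lconst + sp * std::log(t) - s * t);
        out[k] = v;
        area += v;
    }
    area *= dt;
    if (area <= 0) stop("degenerate VTF area");
    for (int k = 0; k < n; ++k) out[k] /= area;
    return out;
}

// Negative log posterior of the Bezier deconvolution model.
// theta = [p1x, p1y, p2x, p2y, p3x, cbf, (delta), (s, p)] per variant flags.
// Data term: N/2 * log(RSS) (Gaussian likelihood, noise variance profiled out);
// prior terms: independent Gaussians; penalty: quadratic exterior penalty
// (weight pen_w) on feasibility-bound violations, on non-monotone dense Bezier x,
// and on increases of the sampled residue.
// [[Rcpp::export]]
double cpp_nlp(NumericVector theta, NumericVector y, NumericVector aif,
               double dt, NumericVector prior_mean, NumericVector prior_sd,
               int delay_on, int disp_on, double kappa, double pen_w) {
    const int n = y.size();
    const int np = 6 + (delay_on ? 1 : 0) + (disp_on ? 2 : 0);
    if (theta.size() != np) stop("theta length does not match variant");
    for (int i = 0; i < np; ++i)
        if (!R_finite(theta[i])) stop("non-finite parameter value");
    double p1x = theta[0], p1y = theta[1], p2x = theta[2], p2y = theta[3],
           p3x = theta[4], cbf = theta[5];
    int idx = 6;
    double delta = 0.0, s = 0.0, p = 0.0;
    if (delay_on) delta = theta[idx++];
    if (disp_on) { s = theta[idx]; p = theta[idx + 1]; }

    double pen = 0.0;
    const double p3min = 0.1;
    double p3e = p3x;
    if (p3e < p3min) { pen += (p3min - p3e) * (p3min - p3e); p3e = p3min; }
    if (p1y < 0) pen += p1y * p1y;
    if (p1y > 1) pen += (p1y - 1) * (p1y - 1);
    if (p2y < 0) pen += p2y * p2y;
    if (p2y > 1) pen += (p2y - 1) * (p2y - 1);
    if (p1x < 0) pen += p1x * p1x;
    if (p1x > p3e) pen += (p1x - p3e) * (p1x - p3e);
    if (p2x < 0) pen += p2x * p2x;
    if (p2x > p3e) pen += (p2x - p3e) * (p2x - p3e);
    if (cbf < 0) pen += cbf * cbf;
    if (delay_on && delta < 0) pen += delta * delta;
    double se = s, pe = p;
    if (disp_on) {
        const double smin = 1e-3;
        if (se < smin) { pen += (smin - se) * (smin - se); se = smin; }
        if (pe < 0) { pen += pe * pe; pe = 0.0; }
    }

    NumericVector ctrl = NumericVector::create(p1x, p1y, p2x, p2y, p3e);
    List res = cpp_bezier_residue(ctrl, dt, n);
    NumericVector R = res["values"];
    pen += as<double>(res["x_violation"]);
    for (int k = 1; k < n; ++k) {
        double d = R[k] - R[k - 1];
        if (d > 0) pen += d * d;
    }

    NumericVector a = aif;
    if (delay_on) a = cpp_shift_curve(a, dt, delta);
    if (disp_on) a = cpp_conv(a, cpp_gamma_vtf(se, pe, dt, n), dt);
    NumericVector m = cpp_conv(a, R, dt);
    double rss = 0.0;
    const double scale = kappa * cbf;
    for (int k = 0; k < n; ++k) {
        double r = y[k] - scale * m[k];
        rss += r * r;
    }
    double obj = 0.5 * n * std::log(rss + 1e-300);
    for (int i = 0; i < np; ++i) {
        double zi = (theta[i] - prior_mean[i]) / prior_sd[i];
        obj += 0.5 * zi * zi;
    }
    return obj + pen_w * pen;
}

// Profiled objective: same posterior as cpp_nlp but with CBF minimized out
// exactly (coordinate minimization; the joint MAP is unchanged). shape_theta
// excludes cbf: [p1x, p1y, p2x, p2y, p3x, (delta), (s, p)]. prior_mean /
// prior_sd are full-length (cbf at index 5). Returns the profiled objective
// value and the minimizing cbf.
// [[Rcpp::export]]
List cpp_nlp_profiled(NumericVector shape_theta, NumericVector y,
                      NumericVector aif, double dt, NumericVector prior_mean,
                      NumericVector prior_sd, int delay_on, int disp_on,
                      double kappa, double pen_w) {
    const int n = y.size();
    const int nshape = 5 + (delay_on ? 1 : 0) + (disp_on ? 2 : 0);
    if (shape_theta.size() != nshape) stop("theta length does not match variant");
    for (int i = 0; i < nshape; ++i)
        if (!R_finite(shape_theta[i])) stop("non-finite parameter value");
    double p1x = shape_theta[0], p1y = shape_theta[1], p2x = shape_theta[2],
           p2y = shape_theta[3], p3x = shape_theta[4];
    int idx = 5;
    double delta = 0.0, s = 0.0, p = 0.0;
    if (delay_on) delta = shape_theta[idx++];
    if (disp_on) { s = shape_theta[idx]; p = shape_theta[idx + 1]; }

    double pen = 0.0;
    const double p3min = 0.1;
    double p3e = p3x;
    if (p3e < p3min) { pen += (p3min - p3e) * (p3min - p3e); p3e = p3min; }
    if (p1y < 0) pen += p1y * p1y;
    if (p1y > 1) pen += (p1y - 1) * (p1y - 1);
    if (p2y < 0) pen += p2y * p2y;
    if (p2y > 1) pen += (p2y - 1) * (p2y - 1);
    if (p1x < 0) pen += p1x * p1x;
    if (p1x > p3e) pen += (p1x - p3e) * (p1x - p3e);
    if (p2x < 0) pen += p2x * p2x;
    if (p2x > p3e) pen += (p2x - p3e) * (p2x - p3e);
    if (delay_on && delta < 0) pen += delta * delta;
    double se = s, pe = p;
    if (disp_on) {
        const double smin = 1e-3;
        if (se < smin) { pen += (smin - se) * (smin - se); se = smin; }
        if (pe < 0) { pen += pe * pe; pe = 0.0; }
    }

    NumericVector ctrl = NumericVector::create(p1x, p1y, p2x, p2y, p3e);
    List res = cpp_bezier_residue(ctrl, dt, n);
    NumericVector R = res["values"];
    pen += as<double>(res["x_violation"]);
    for (int k = 1; k < n; ++k) {
        double d = R[k] - R[k - 1];
        if (d > 0) pen += d * d;
    }

    NumericVector a = aif;
    if (delay_on) a = cpp_shift_curve(a, dt, delta);
    if (disp_on) a = cpp_conv(a, cpp_gamma_vtf(se, pe, dt, n), dt);
    NumericVector m = cpp_conv(a, R, dt);
    // RSS(c) = yy - 2 c ym + c^2 mm, c = cbf, model = kappa * c * m
    double yy = 0.0, ym = 0.0, mm = 0.0;
    for (int k = 0; k < n; ++k) {
        double mk = kappa * m[k];
        yy += y[k] * y[k];
        ym += y[k] * mk;
        mm += mk * mk;
    }
    const double m0 = prior_mean[5], s0 = prior_sd[5];
    double c = (mm > 0) ? ym / mm : 0.0;   // least-squares start
    if (c < 0) c = 0.0;
    // Newton on g(c) = n/2 log RSS(c) + ((c - m0)/s0)^2 / 2 + pen_w * min(c,0)^2
    for (int it = 0; it < 8; ++it) {
        double rssc = yy - 2.0 * c * ym + c * c * mm + 1e-300;
        double d1 = 0.5 * n * (2.0 * c * mm - 2.0 * ym) / rssc +
            (c - m0) / (s0 * s0);
        double d2 = 0.5 * n * (2.0 * mm / rssc -
            std::pow((2.0 * c * mm - 2.0 * ym) / rssc, 2.0)) +
            1.0 / (s0 * s0);
        if (c < 0) { d1 += 2.0 * pen_w * c; d2 += 2.0 * pen_w; }
        if (!(d2 > 0)) break;
        double step = d1 / d2;
        c -= step;
        if (std::fabs(step) < 1e-12 * (std::fabs(c) + 1e-12)) break;
    }
    if (c < 0) c = 0.0;
    double rss = yy - 2.0 * c * ym + c * c * mm;
    if (rss < 0) rss = 0.0;
    double obj = 0.5 * n * std::log(rss + 1e-300);
    double zc = (c - m0) / s0;
    obj += 0.5 * zc * zc;
    for (int i = 0; i < nshape; ++i) {
        int pi = (i < 5) ? i : i + 1;  // skip the cbf slot in the priors
        double zi = (shape_theta[i] - prior_mean[pi]) / prior_sd[pi];
        obj += 0.5 * zi * zi;
    }
    return List::create(_["value"] = obj + pen_w * pen, _["cbf"] = c);
}
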