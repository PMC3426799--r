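network tree8 {
}
variable X1 {
  type discrete [ 2 ] { s1, s2 };
}
variable X2 {
  type discrete [ 3 ] { s1, s2, s3 };
}
variable X3 {
  type discrete [ 2 ] { s1, s2 };
}
variable X4 {
  type discrete [ 3 ] { s1, s2, s3 };
}
variable X5 {
  type discrete [ 2 ] { s1, s2 };
}
variable X6 {
  type discrete [ 3 ] { s1, s2, s3 };
}
variable X7 {
  type discrete [ 2 ] { s1, s2 };
}
variable X8 {
  type discrete [ 3 ] { s1, s2, s3 };
}
probability ( X1 ) {
  table 0.045160086169479592, 0.95483991383052047;
}
probability ( X2 | X1 ) {
  ( s1 ) 0.9429139613284433, 0.052898277780778449, 0.0041877608907782866;
  ( s2 ) 0.16056088379540864, 0.83942666653301568, 1.2449671575638339e-05;
}
probability ( X3 | X1 ) {
  ( s1 ) 5.5678743128680313e-11, 0.99999999994432132;
  ( s2 ) 0.1938167870386831, 0.8061832129613169;
}
probability ( X4 | X2 ) {
  ( s1 ) 0.1454355091666682, 0.78286035869986514, 0.071704132133466644;
  ( s2 ) 0.032393601956398968, 0.46053868485545901, 0.50706771318814203;
  ( s3 ) 0.055847108152666913, 0.77230321091661314, 0.17184968093072003;
}
probability ( X5 | X1 ) {
  ( s1 ) 0.35875581135927215, 0.64124418864072774;
  ( s2 ) 0.12629379768086366, 0.87370620231913632;
}
probability ( X6 | X1 ) {
  ( s1 ) 0.45545991873553154, 0.00057470172783397381, 0.54396537953663449;
  ( s2 ) 0.0063888261225050532, 0.99202796081223543, 0.0015832130652595989;
}
probability ( X7 | X5 ) {
  ( s1 ) 0.049996919018304407, 0.9500030809816955;
  ( s2 ) 0.28708336065649914, 0.71291663934350091;
}
probability ( X8 | X3 ) {
  ( s1 ) 0.023489507095083014, 0.97545872082625806, 0.0010517720786589559;
  ( s2 ) 0.156599443163317, 0.84339603425811382, 4.5225785690353138e-06;
}
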