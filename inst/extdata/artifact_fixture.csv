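"trial","channel","sample","uV"
1,"Cz",1,19.6
1,"Cz",2,9.4
1,"Cz",3,-2.2
1,"Cz",4,-4.3
1,"Cz",5,23.2
1,"Cz",6,25.8
1,"Cz",7,10.7
1,"Cz",8,-2.5
1,"Cz",9,-24.5
1,"Cz",10,-22.4
1,"Cz",11,-33.4
1,"Cz",12,9.4
1,"Cz",13,250
1,"Cz",14,5.9
1,"Cz",15,-65.5
1,"Cz",16,-3
1,"Cz",17,-18.6
1,"Cz",18,9.1
1,"Cz",19,-32.1
1,"Cz",20,-40.2
1,"Cz",21,22.8
1,"Cz",22,6.3
1,"Cz",23,20.9
1,"Cz",24,-4.3
1,"Cz",25,7.9
1,"Pz",1,-30.9
1,"Pz",2,-2.4
1,"Pz",3,13.7
1,"Pz",4,-41.1
1,"Pz",5,-2.2
1,"Pz",6,-28.8
1,"Pz",7,-6.5
1,"Pz",8,-10.1
1,"Pz",9,24.1
1,"Pz",10,-10
1,"Pz",11,7.8
1,"Pz",12,6.7
1,"Pz",13,-9.8
1,"Pz",14,-11.4
1,"Pz",15,8.6
1,"Pz",16,-17.4
1,"Pz",17,-0.1
1,"Pz",18,9.9
1,"Pz",19,39.5
1,"Pz",20,-23.9
1,"Pz",21,2.6
1,"Pz",22,6.6
1,"Pz",23,13.4
1,"Pz",24,12.8
1,"Pz",25,38.8
2,"Cz",1,-11.1
2,"Cz",2,-15.3
2,"Cz",3,-12.9
2,"Cz",4,-20.6
2,"Cz",5,-13.6
2,"Cz",6,-28.7
2,"Cz",7,17.9
2,"Cz",8,-4.8
2,"Cz",9,20
2,"Cz",10,-0.7
2,"Cz",11,31.9
2,"Cz",12,17.2
2,"Cz",13,200
2,"Cz",14,3.5
2,"Cz",15,32.9
2,"Cz",16,-2.6
2,"Cz",17,-39.9
2,"Cz",18,14.3
2,"Cz",19,9.8
2,"Cz",20,-42.4
2,"Cz",21,22.6
2,"Cz",22,-24.2
2,"Cz",23,5.9
2,"Cz",24,1.5
2,"Cz",25,3.9
2,"Pz",1,-6.3
2,"Pz",2,28.4
2,"Pz",3,13.7
2,"Pz",4,-20.8
2,"Pz",5,0.3
2,"Pz",6,-24.9
2,"Pz",7,19.8
2,"Pz",8,17.3
2,"Pz",9,-35.1
2,"Pz",10,3
2,"Pz",11,22.2
2,"Pz",12,-3.7
2,"Pz",13,-5.1
2,"Pz",14,-5
2,"Pz",15,16.3
2,"Pz",16,-24.5
2,"Pz",17,-10.4
2,"Pz",18,-14.1
2,"Pz",19,13.7
2,"Pz",20,11
2,"Pz",21,-41.3
2,"Pz",22,-23.3
2,"Pz",23,-23.6
2,"Pz",24,-0.6
2,"Pz",25,23
3,"Cz",1,44.2
3,"Cz",2,8.8
3,"Cz",3,20.9
3,"Cz",4,2.5
3,"Cz",5,-25.3
3,"Cz",6,7.5
3,"Cz",7,-4
3,"Cz",8,23.1
3,"Cz",9,-11.2
3,"Cz",10,-22.8
3,"Cz",11,-25.9
3,"Cz",12,22.5
3,"Cz",13,-250
3,"Cz",14,-0.6
3,"Cz",15,-12.5
3,"Cz",16,-36.6
3,"Cz",17,38.1
3,"Cz",18,10.6
3,"Cz",19,-5.3
3,"Cz",20,18.1
3,"Cz",21,-5.3
3,"Cz",22,-6.6
3,"Cz",23,-26.1
3,"Cz",24,-3.9
3,"Cz",25,-14.2
3,"Pz",1,0.6
3,"Pz",2,-21.5
3,"Pz",3,-21.8
3,"Pz",4,-11.4
3,"Pz",5,10.4
3,"Pz",6,-19.4
3,"Pz",7,2.7
3,"Pz",8,-13
3,"Pz",9,0.7
3,"Pz",10,33.8
3,"Pz",11,-16.9
3,"Pz",12,-24
3,"Pz",13,10.6
3,"Pz",14,6.5
3,"Pz",15,-6
3,"Pz",16,11
3,"Pz",17,-24.9
3,"Pz",18,-15.9
3,"Pz",19,34.9
3,"Pz",20,17.3
3,"Pz",21,14.6
3,"Pz",22,34.7
3,"Pz",23,2.8
3,"Pz",24,17.4
3,"Pz",25,21
4,"Cz",1,-22.7
4,"Cz",2,-0.9
4,"Cz",3,47.9
4,"Cz",4,24.9
4,"Cz",5,-15.3
4,"Cz",6,-59
4,"Cz",7,6.6
4,"Cz",8,-6.1
4,"Cz",9,-14.3
4,"Cz",10,5.8
4,"Cz",11,34.8
4,"Cz",12,-0.1
4,"Cz",13,150
4,"Cz",14,31.2
4,"Cz",15,-7.6
4,"Cz",16,-12.7
4,"Cz",17,2.7
4,"Cz",18,-34.5
4,"Cz",19,24.5
4,"Cz",20,43.9
4,"Cz",21,-7.4
4,"Cz",22,18.5
4,"Cz",23,-9.8
4,"Cz",24,4.2
4,"Cz",25,8
4,"Pz",1,23.1
4,"Pz",2,24.8
4,"Pz",3,3.3
4,"Pz",4,14.3
4,"Pz",5,-7.6
4,"Pz",6,13.9
4,"Pz",7,5.1
4,"Pz",8,13.4
4,"Pz",9,-13.3
4,"Pz",10,-7.5
4,"Pz",11,15
4,"Pz",12,19.9
4,"Pz",13,-7.2
4,"Pz",14,-13.4
4,"Pz",15,9.6
4,"Pz",16,-11.8
4,"Pz",17,-20.9
4,"Pz",18,11.1
4,"Pz",19,21.3
4,"Pz",20,25.8
4,"Pz",21,11.7
4,"Pz",22,25.3
4,"Pz",23,9.8
4,"Pz",24,45.9
4,"Pz",25,-36.3
5,"Cz",1,0
5,"Cz",2,9.5
5,"Cz",3,-15.6
5,"Cz",4,4.1
5,"Cz",5,20.5
5,"Cz",6,-20.2
5,"Cz",7,-15
5,"Cz",8,2.9
5,"Cz",9,17.6
5,"Cz",10,8.6
5,"Cz",11,-13.8
5,"Cz",12,11.2
5,"Cz",13,-199.9
5,"Cz",14,-54.8
5,"Cz",15,12.9
5,"Cz",16,8
5,"Cz",17,14
5,"Cz",18,10.4
5,"Cz",19,-11.9
5,"Cz",20,21.6
5,"Cz",21,-13
5,"Cz",22,29.9
5,"Cz",23,2.7
5,"Cz",24,-1.5
5,"Cz",25,0.5
5,"Pz",1,4.8
5,"Pz",2,-1.7
5,"Pz",3,9.2
5,"Pz",4,-5.1
5,"Pz",5,12.3
5,"Pz",6,26.9
5,"Pz",7,13.5
5,"Pz",8,-4.4
5,"Pz",9,-7.5
5,"Pz",10,-0.6
5,"Pz",11,1.7
5,"Pz",12,-1.3
5,"Pz",13,-10.3
5,"Pz",14,1.6
5,"Pz",15,-18.3
5,"Pz",16,4.3
5,"Pz",17,21.8
5,"Pz",18,27.3
5,"Pz",19,22.7
5,"Pz",20,-18.2
5,"Pz",21,37.8
5,"Pz",22,-11.3
5,"Pz",23,5.2
5,"Pz",24,-22.4
5,"Pz",25,3.1
6,"Cz",1,34.6
6,"Cz",2,3.4
6,"Cz",3,20.5
6,"Cz",4,-5.6
6,"Cz",5,5.4
6,"Cz",6,-31.5
6,"Cz",7,3
6,"Cz",8,-3.2
6,"Cz",9,11
6,"Cz",10,-23
6,"Cz",11,-4.8
6,"Cz",12,-6.9
6,"Cz",13,201
6,"Cz",14,-15.1
6,"Cz",15,-50.8
6,"Cz",16,12.2
6,"Cz",17,-9.1
6,"Cz",18,14.6
6,"Cz",19,10.8
6,"Cz",20,18.5
6,"Cz",21,17.9
6,"Cz",22,-3.6
6,"Cz",23,-26.8
6,"Cz",24,-16.3
6,"Cz",25,11.4
6,"Pz",1,0.6
6,"Pz",2,-12.4
6,"Pz",3,-31.8
6,"Pz",4,-18.7
6,"Pz",5,-2.4
6,"Pz",6,13.3
6,"Pz",7,4.8
6,"Pz",8,27.3
6,"Pz",9,4.5
6,"Pz",10,12.2
6,"Pz",11,-7.8
6,"Pz",12,-15.6
6,"Pz",13,1.3
6,"Pz",14,21.9
6,"Pz",15,50.7
6,"Pz",16,-13.8
6,"Pz",17,16.1
6,"Pz",18,33.2
6,"Pz",19,-8.3
6,"Pz",20,6.8
6,"Pz",21,14.1
6,"Pz",22,26.3
6,"Pz",23,-24.6
6,"Pz",24,-25.5
6,"Pz",25,2.7
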